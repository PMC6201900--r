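#' Per-reaction summaries of populated ensembles
#'
#' Computes, for every ensemble, the per-reaction median and standard
#' deviation of steady-state fluxes and (optionally) of the kinetic
#' constants of the member parametrizations.  Two grouping modes are
#' supported: `"by_condition"` (sC columns; records grouped by the
#' condition they were simulated under, restricted to runs that reached
#' steady state) and `"by_filter"` (fC columns; records grouped by the
#' phenotypes their flux distribution satisfies, disregarding the
#' simulated condition, so one record can contribute to several groups).
#'
#' @param records A wide record table as returned by [run_ensemble()]
#'   (columns `parametrization_id`, `condition_id`, `passed`, plus one
#'   numeric flux column per reaction).
#' @param membership Membership tibble from [assign_phenotypes()];
#'   required for `grouping_mode = "by_filter"`.
#' @param params Optional parametrization table
#'   ([sample_parametrizations()]); when given, kinetic-constant medians
#'   and standard deviations are included.
#' @param grouping_mode `"by_condition"` or `"by_filter"`.
#' @return A tibble with columns `group_id`, `grouping_mode`, `empty`,
#'   `n_members`, `reaction_id`, `flux_median`, `flux_sd` and, when
#'   `params` is supplied, `k_median`, `k_sd`.  Empty ensembles appear
#'   with `empty = TRUE` and no statistics rows beyond a placeholder.
#' @export
summarize_ensembles <- function(records, membership = NULL, params = NULL,
                                grouping_mode = c("by_condition", "by_filter")) {
  grouping_mode <- arg_match(grouping_mode)
  id_cols <- c("parametrization_id", "condition_id", "seed", "statistic",
               "passed", "solver_ok", "record_id")
  rx_cols <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                     id_cols)
  steady <- records[!is.na(records$passed) & records$passed, , drop = FALSE]
  groups <- if (grouping_mode == "by_condition") {
    split(steady, steady$condition_id)
  } else {
    if (is.null(membership)) {
      abort("`by_filter` grouping needs a membership table.",
            class = "kin_validation_error")
    }
    ph_cols <- setdiff(names(membership),
                       c("record_id", "parametrization_id", "condition_id"))
    key <- c("parametrization_id", "condition_id")
    joined <- left_join(steady, membership, by = intersect(key, names(membership)))
    stats::setNames(
      map(ph_cols, function(p) joined[!is.na(joined[[p]]) & joined[[p]], ,
                                      drop = FALSE]),
      ph_cols
    )
  }
  kmat <- if (!is.null(params)) params else NULL
  out <- imap(groups, function(g, gid) {
    if (nrow(g) == 0L) {
      return(tibble(group_id = gid, grouping_mode = grouping_mode,
                    empty = TRUE, n_members = 0L, reaction_id = NA_character_,
                    flux_median = NA_real_, flux_sd = NA_real_))
    }
    res <- tibble(
      group_id = gid, grouping_mode = grouping_mode, empty = FALSE,
      n_members = nrow(g),
      reaction_id = rx_cols,
      flux_median = unname(vapply(rx_cols, function(r) median(g[[r]]), numeric(1))),
      flux_sd = unname(vapply(rx_cols, function(r) sd(g[[r]]), numeric(1)))
    )
    if (!is.null(kmat)) {
      kg <- kmat[kmat$parametrization_id %in% unique(g$parametrization_id), ,
                 drop = FALSE]
      krx <- intersect(rx_cols, names(kg))
      res$k_median <- unname(vapply(res$reaction_id, function(r) {
        if (r %in% krx) median(kg[[r]]) else NA_real_
      }, numeric(1)))
      res$k_sd <- unname(vapply(res$reaction_id, function(r) {
        if (r %in% krx) sd(kg[[r]]) else NA_real_
      }, numeric(1)))
    }
    res
  })
  bind_rows(out)
}

ks_pair <- function(x, y, exact_max_n = 50L) {
  exact <- length(x) <= exact_max_n && length(y) <= exact_max_n
  ht <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Identify fluxes that discriminate every pair of conditions
#'
#' Runs a two-sample Kolmogorov-Smirnov test for every reaction and every
#' unordered pair of conditions.  A reaction is *relevant* iff its flux
#' distributions differ significantly (`p < alpha`) for **all** pairs.
#' Exact p-values are used when both samples have at most 50
#' observations, asymptotic ones otherwise.  Pairs where either condition
#' has fewer than 2 samples are skipped and reported; such a reaction can
#' never be relevant.  No multiple-testing correction is applied by
#' default; Benjamini-Hochberg is available via `p_adjust = "BH"`.
#'
#' @param samples Either a long tibble with columns `condition_id`,
#'   `reaction_id`, `value`, or a wide record table with a `condition_id`
#'   column and one numeric column per reaction.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or any method of
#'   [stats::p.adjust()], applied across all computed p-values.
#' @return A `ks_report`: list with `pairwise` (tibble `reaction_id`,
#'   `cond_a`, `cond_b`, `n_a`, `n_b`, `statistic`, `p_value`,
#'   `skipped`), `relevant` (character vector), `alpha`, `p_adjust`.
#' @export
ks_relevant_fluxes <- function(samples, alpha = 0.05, p_adjust = "none") {
  long <- if (all(c("reaction_id", "value", "condition_id") %in% names(samples))) {
    as_tibble(samples)
  } else {
    if (!"condition_id" %in% names(samples)) {
      abort("`samples` needs a condition_id column.",
            class = "kin_validation_error")
    }
    id_cols <- intersect(c("parametrization_id", "condition_id", "record_id",
                           "seed", "statistic", "passed", "solver_ok"),
                         names(samples))
    rx <- setdiff(names(samples)[vapply(samples, is.numeric, logical(1))], id_cols)
    tidyr::pivot_longer(samples[, c("condition_id", rx)], cols = all_of(rx),
                        names_to = "reaction_id", values_to = "value")
  }
  long <- long[!is.na(long$value), , drop = FALSE]
  conds <- sort(unique(long$condition_id))
  if (length(conds) < 2L) {
    abort("Need at least two conditions for pairwise KS tests.",
          class = "kin_validation_error")
  }
  pairs <- utils::combn(conds, 2L, simplify = FALSE)
  reactions <- sort(unique(long$reaction_id))
  by_cond <- split(long, long$condition_id)
  rows <- list()
  for (r in reactions) {
    vals <- map(by_cond, function(tbl) tbl$value[tbl$reaction_id == r])
    for (pr in pairs) {
      x <- vals[[pr[1]]]; y <- vals[[pr[2]]]
      if (length(x) < 2L || length(y) < 2L) {
        rows[[length(rows) + 1L]] <- tibble(
          reaction_id = r, cond_a = pr[1], cond_b = pr[2],
          n_a = length(x), n_b = length(y),
          statistic = NA_real_, p_value = NA_real_, skipped = TRUE)
      } else {
        kt <- ks_pair(x, y)
        rows[[length(rows) + 1L]] <- tibble(
          reaction_id = r, cond_a = pr[1], cond_b = pr[2],
          n_a = length(x), n_b = length(y),
          statistic = kt$statistic, p_value = kt$p_value, skipped = FALSE)
      }
    }
  }
  pairwise <- bind_rows(rows)
  if (!identical(p_adjust, "none")) {
    ok <- !pairwise$skipped
    pairwise$p_value[ok] <- stats::p.adjust(pairwise$p_value[ok],
                                            method = p_adjust)
  }
  report <- structure(list(pairwise = pairwise, alpha = alpha,
                           p_adjust = p_adjust,
                           n_conditions = length(conds)),
                      class = "ks_report")
  report$relevant <- ks_relevant_at(report, alpha)
  report
}

#' Relevant set of a KS report at a different significance level
#'
#' The relevant set is non-decreasing in `alpha`.
#'
#' @param report A `ks_report`.
#' @param alpha Significance level.
#' @return Character vector of relevant reaction ids.
#' @export
ks_relevant_at <- function(report, alpha) {
  pw <- report$pairwise
  by_rx <- split(pw, pw$reaction_id)
  rel <- map_lgl(by_rx, function(tbl) {
    !any(tbl$skipped) && all(tbl$p_value < alpha)
  })
  sort(names(rel)[rel])
}

#' @export
print.ks_report <- function(x, ...) {
  cat("<ks_report> ", length(unique(x$pairwise$reaction_id)), " reactions x ",
      nrow(x$pairwise) / max(1L, length(unique(x$pairwise$reaction_id))),
      " condition pairs; ", length(x$relevant),
      " relevant at alpha = ", format(x$alpha), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ks_report <- function(x, ...) {
  x$pairwise
}

#' @export
glance.ks_report <- function(x, ...) {
  tibble(alpha = x$alpha, p_adjust = x$p_adjust,
         n_conditions = x$n_conditions,
         n_reactions = length(unique(x$pairwise$reaction_id)),
         n_relevant = length(x$relevant),
         n_skipped_pairs = sum(x$pairwise$skipped))
}
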