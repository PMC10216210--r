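#' Initial three-candidate grids for the hyperparameter search
#'
#' Builds the round-0 candidate grid of the coordinate-wise search: for the
#' kernel counts `nk1`, `nk2` and the kernel width `k2` the triple is
#' `(k, 2k, 8k)` with base `k = nch`; the stride `s2` is searched as a
#' fraction of each combination's `k2`, with candidate ratios
#' `(1/8, 1/4, 1)` -- so every enumerated combination automatically
#' satisfies `s2 <= k2` and the full `3^5` product survives; `nfb` is
#' searched over an explicit candidate list (default `c(1, 3, 7)`), not
#' ratio-generated. `k2` candidates are clamped to `2 * n_bins * nfb` (at
#' the largest `nfb` candidate).
#'
#' @param nch Channel count (sets the ratio base).
#' @param nfb_candidates Explicit sub-band-count candidates.
#' @param n_bins Retained FFT bins, for the `k2` clamp.
#' @return An object of class `agd_grid`: named list of candidate value
#'   vectors for `nfb`, `nk1`, `nk2`, `k2` and stride ratios `s2`, the
#'   round index (0), the clamp context, and `s2_is_ratio = TRUE` marking
#'   the stride grid as relative. Hand-built grids may instead supply
#'   absolute `s2` values with `s2_is_ratio = FALSE`.
#' @examples
#' init_grids(8)
#' @export
init_grids <- function(nch, nfb_candidates = c(1L, 3L, 7L), n_bins = 110L) {
  nch <- as.integer(nch)
  stopifnot(nch >= 1L, length(nfb_candidates) >= 1L)
  ratio <- c(1L, 2L, 8L) * nch
  k2_max <- 2L * as.integer(n_bins) * max(nfb_candidates)
  structure(
    list(grids = list(nfb = as.integer(sort(nfb_candidates)),
                      nk1 = ratio, nk2 = ratio,
                      k2 = as.integer(pmin(ratio, k2_max)),
                      s2 = c(1 / 8, 1 / 4, 1)),
         round = 0L, nch = nch, n_bins = as.integer(n_bins),
         s2_is_ratio = TRUE),
    class = "agd_grid"
  )
}

#' Realize stride candidates at a given kernel width
#'
#' @param grid An [init_grids()] grid.
#' @param k2 Kernel width at which to realize the stride ratios.
#' @return Integer stride values, rounded half-up and clamped to `k2`.
#' @export
realize_s2 <- function(grid, k2) {
  stopifnot(inherits(grid, "agd_grid"))
  if (!isTRUE(grid$s2_is_ratio)) return(as.integer(grid$grids$s2))
  as.integer(pmin(pmax(round_half_up(grid$grids$s2 * k2), 1L), k2))
}

#' @export
print.agd_grid <- function(x, ...) {
  cat(sprintf("<agd_grid round %d>\n", x$round))
  for (nm in names(x$grids)) {
    cat(sprintf("  %-4s: %s\n", nm, paste(x$grids[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Enumerate one search round
#'
#' Takes the Cartesian product of the per-hyperparameter candidate values.
#' With a ratio-based stride grid (the default, see [init_grids()]) the
#' stride of each combination is `round(ratio * k2)` clamped to `[1, k2]`,
#' so the full product (3^5 = 243 for the standard grids) is valid. With an
#' absolute stride grid, combinations violating `k2 <= 2 * n_bins * nfb` or
#' `s2 <= k2` are dropped and counted.
#'
#' @param grid An [init_grids()] object (or later-round grid).
#' @param n_bins Retained FFT bins used for the `k2` constraint; defaults to
#'   the grid's own clamp context.
#' @return A tibble with columns `nfb`, `nk1`, `nk2`, `k2`, `s2` (realized
#'   stride) and, for ratio grids, `s2_ratio`; one row per valid
#'   combination in deterministic enumeration order; attribute `n_removed`
#'   counts the clamp-removed combinations.
#' @examples
#' nrow(enumerate_round(init_grids(8)))
#' @export
enumerate_round <- function(grid, n_bins = NULL) {
  stopifnot(inherits(grid, "agd_grid"))
  if (is.null(n_bins)) n_bins <- grid$n_bins
  combos <- tibble::as_tibble(
    do.call(expand.grid, c(grid$grids, KEEP.OUT.ATTRS = FALSE)))
  if (isTRUE(grid$s2_is_ratio)) {
    combos$s2_ratio <- combos$s2
    combos$s2 <- as.integer(pmin(pmax(round_half_up(combos$s2_ratio *
                                                    combos$k2), 1L),
                                 combos$k2))
  } else {
    combos$s2 <- as.integer(combos$s2)
  }
  ok <- combos$k2 <= 2L * n_bins * combos$nfb & combos$s2 <= combos$k2
  removed <- sum(!ok)
  out <- combos[ok, ]
  if (nrow(out) == 0L) {
    stop("no valid hyperparameter combinations after clamping", call. = FALSE)
  }
  attr(out, "n_removed") <- removed
  out
}

#' Marginal performance trend of one hyperparameter
#'
#' Given a round's evaluated combinations, looks at the three combinations
#' that differ from `anchor` only in hyperparameter `param` (one per
#' candidate value, in ascending value order) and classifies the ordering of
#' their performances: strictly rising is `"increasing"`, strictly falling
#' is `"decreasing"`, everything else (including ties) is `"peaked"` -- the
#' conservative refinement.
#'
#' @param results A tibble with the hyperparameter columns and a `metric`
#'   performance column (default `test_acc`).
#' @param param Hyperparameter name.
#' @param anchor Named list/row giving the anchor values of the other
#'   hyperparameters.
#' @param values The three candidate values; default the sorted unique
#'   values of `param` among the matching rows.
#' @param metric Performance column name.
#' @return `"increasing"`, `"peaked"` or `"decreasing"`, with attribute
#'   `performance` holding the three metric values.
#' @export
marginal_trend <- function(results, param, anchor, values = NULL,
                           metric = "test_acc") {
  col <- if (param == "s2" && "s2_ratio" %in% names(results)) {
    "s2_ratio"          # ratio-based stride grids vary the ratio, not s2
  } else {
    param
  }
  others <- setdiff(c("nfb", "nk1", "nk2", "k2", "s2"), param)
  sel <- rep(TRUE, nrow(results))
  for (nm in others) sel <- sel & results[[nm]] == anchor[[nm]]
  sub <- results[sel, ]
  if (is.null(values)) values <- sort(unique(sub[[col]]))
  perf <- vapply(values, function(v) {
    row <- sub[abs(sub[[col]] - v) < 1e-12, ]
    if (nrow(row) == 0L) {
      stop(sprintf("missing combination for %s = %s", param, v), call. = FALSE)
    }
    row[[metric]][1]
  }, 0)
  if (length(perf) != 3L) {
    stop("marginal trend needs exactly three candidate values", call. = FALSE)
  }
  trend <- if (perf[1] < perf[2] && perf[2] < perf[3]) {
    "increasing"
  } else if (perf[1] > perf[2] && perf[2] > perf[3]) {
    "decreasing"
  } else {
    "peaked"
  }
  structure(trend, performance = perf)
}

#' Next candidate triple from a trend
#'
#' The three grid update rules of the search: an increasing trend shifts the
#' grid up, `(a2, 2*a2, 8*a2)`; a peaked trend refines around the middle,
#' `((a0+a1)/2, a1, (a1+a2)/2)`; a decreasing trend shifts down,
#' `(a0/8, a0/2, a0)`. If the trend reversed relative to the previous round
#' (oscillation), the refine rule is applied instead. Values are rounded
#' half-up to integers of at least 1, strict ordering is restored by
#' incrementing collisions, and the triple is re-clamped to `upper` if
#' given; a triple that collapses under clamping is flagged `frozen` (all
#' values equal to the clamp).
#'
#' @param triple Numeric ascending triple `(a0, a1, a2)`.
#' @param trend `"increasing"`, `"peaked"` or `"decreasing"`.
#' @param prev_trend Trend of the previous round, for the oscillation guard.
#' @param upper Optional upper clamp for the values.
#' @param integer Round to distinct integers (`TRUE`, the default, for
#'   counts and widths); `FALSE` keeps continuous values (stride ratios).
#' @return Numeric triple (integer-valued when `integer = TRUE`); attribute
#'   `frozen` is `TRUE` if the triple collapsed under clamping.
#' @examples
#' next_grid(c(8, 16, 64), "peaked")
#' @export
next_grid <- function(triple, trend, prev_trend = NULL, upper = NULL,
                      integer = TRUE) {
  stopifnot(length(triple) == 3L, all(diff(triple) > 0))
  trend <- match.arg(trend, c("increasing", "peaked", "decreasing"))
  reversed <- !is.null(prev_trend) &&
    ((trend == "increasing" && prev_trend == "decreasing") ||
     (trend == "decreasing" && prev_trend == "increasing"))
  rule <- if (reversed) "peaked" else trend
  a <- as.numeric(triple)
  new <- switch(rule,
    increasing = c(a[3], 2 * a[3], 8 * a[3]),
    peaked = c((a[1] + a[2]) / 2, a[2], (a[2] + a[3]) / 2),
    decreasing = c(a[1] / 8, a[1] / 2, a[1])
  )
  if (integer) {
    new <- pmax(round_half_up(new), 1)
    for (j in 2:3) if (new[j] <= new[j - 1]) new[j] <- new[j - 1] + 1
  }
  frozen <- FALSE
  if (!is.null(upper)) {
    new <- pmin(new, upper)
    if (any(duplicated(new))) {
      frozen <- TRUE
      new <- rep(max(new), 3L)
    }
  }
  if (integer) new <- as.integer(new)
  structure(new, frozen = frozen)
}

#' Select seed hyperparameter sets from a round
#'
#' Deterministic stand-in for the manual selection step: combinations are
#' ranked by test accuracy, ties broken by higher training accuracy, then
#' lower loss, then enumeration order, and the top `top_m` are returned.
#' With `interactive = TRUE` in an interactive session the ranked table is
#' printed and a manual choice is accepted.
#'
#' @param results Round results: a tibble with hyperparameter columns and
#'   `test_acc` (optionally `train_acc`, `loss`).
#' @param top_m Number of seed sets to keep (default 2).
#' @param interactive Offer a manual override at the console.
#' @return Tibble of the selected rows, best first.
#' @export
select_seed_sets <- function(results, top_m = 2L, interactive = FALSE) {
  stopifnot(nrow(results) >= 1L)
  if (top_m > nrow(results)) {
    warning("fewer combinations than top_m; returning all", call. = FALSE)
    top_m <- nrow(results)
  }
  train_acc <- results$train_acc %||% rep(0, nrow(results))
  loss <- results$loss %||% rep(0, nrow(results))
  ord <- order(-results$test_acc, -train_acc, loss, seq_len(nrow(results)))
  ranked <- results[ord, ]
  if (interactive && base::interactive()) {
    print(utils::head(ranked, 10))
    ans <- readline(sprintf("rows to keep [default 1:%d]: ", top_m))
    if (nzchar(ans)) {
      keep <- as.integer(strsplit(ans, "[,; ]+")[[1]])
      return(ranked[keep, ])
    }
  }
  ranked[seq_len(top_m), ]
}

#' Stopping rule for the search
#'
#' Stops when the best test accuracy improved by less than `tol_pct`
#' percentage points between the last two completed rounds. With fewer than
#' two rounds the search continues.
#'
#' @param best_by_round Numeric vector, best test accuracy per round.
#' @param tol_pct Improvement threshold in percentage points.
#' @return Logical: `TRUE` to stop.
#' @examples
#' should_stop(c(70, 78))   # improvement 8 -> continue
#' should_stop(c(78.6, 79)) # improvement 0.4 -> stop
#' @export
should_stop <- function(best_by_round, tol_pct = 1.0) {
  n <- length(best_by_round)
  if (n < 2L) return(FALSE)
  (best_by_round[n] - best_by_round[n - 1L]) < tol_pct
}

#' Hyperparameter / performance correlations
#'
#' Pearson correlation of each hyperparameter with test accuracy, training
#' accuracy and loss over all evaluated combinations, plus a pairwise export
#' with test accuracy min-max normalized to `[0, 1]`. A zero-variance
#' hyperparameter column yields `NA` correlations flagged `undefined`, not
#' zero.
#'
#' @param results Tibble of evaluated combinations with columns `nfb`,
#'   `nk1`, `nk2`, `k2`, `s2`, `test_acc` and optionally `train_acc`,
#'   `loss`.
#' @return List of class `agd_correlations`: `correlations` (tibble:
#'   `param`, `metric`, `r`, `undefined`) and `pairwise` (the input with
#'   `test_acc_norm` added).
#' @export
hyperparam_correlations <- function(results) {
  if (nrow(results) < 3L) {
    stop("need at least three evaluated combinations", call. = FALSE)
  }
  params <- intersect(c("nfb", "nk1", "nk2", "k2", "s2"), names(results))
  metrics <- intersect(c("test_acc", "train_acc", "loss"), names(results))
  rows <- list()
  for (p in params) {
    for (m in metrics) {
      undef <- sd(results[[p]]) == 0 || sd(results[[m]]) == 0
      r <- if (undef) NA_real_ else cor(results[[p]], results[[m]])
      rows[[length(rows) + 1L]] <- tibble::tibble(param = p, metric = m,
                                                  r = r, undefined = undef)
    }
  }
  rng <- range(results$test_acc)
  pairwise <- results
  pairwise$test_acc_norm <- if (diff(rng) == 0) {
    rep(0, nrow(results))
  } else {
    (results$test_acc - rng[1]) / diff(rng)
  }
  structure(list(correlations = dplyr::bind_rows(rows), pairwise = pairwise),
            class = "agd_correlations")
}

#' @export
print.agd_correlations <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$correlations[, c("param", "metric", "r")],
                             names_from = "metric", values_from = "r")
  cat("<agd_correlations>\n")
  print(as.data.frame(wide), digits = 3)
  invisible(x)
}

searchable_params <- c("nk1", "nk2", "k2", "s2")

#' Run the coordinate-wise hyperparameter search
#'
#' Drives the full search: round 0 enumerates the initial grids and
#' evaluates every combination with `objective`; the top `top_m` seed sets
#' are selected; for each seed set and each ratio-searched hyperparameter
#' (`nk1`, `nk2`, `k2`, `s2` -- `nfb` is frozen at the seed's value) the
#' marginal trend around the seed picks one of the three grid update rules;
#' the refined grids are enumerated and evaluated in the next round.
#' The search stops after `rounds` rounds or when [should_stop()] fires.
#'
#' @param objective Function taking one [hyperparam_set()] and returning a
#'   list or named vector with `test_acc` (and optionally `train_acc`,
#'   `loss`). Evaluations are memoized within the run, so re-enumerated
#'   combinations are not retrained.
#' @param nch Channel count for [init_grids()].
#' @param n_bins Retained FFT bins (clamp context).
#' @param nfb_candidates Sub-band candidates for round 0.
#' @param rounds Maximum number of additional rounds after round 0.
#' @param top_m Seed sets per round.
#' @param tol_pct Stopping threshold, see [should_stop()].
#' @param params Hyperparameters refined between rounds.
#' @param verbose Print per-round progress.
#' @return An object of class `agd_state`: list with `rounds` (per round:
#'   `grids`, `results` tibble, `seeds`, `trends`), `best_by_round`,
#'   `stopped_early`, and `best` (the best combination overall).
#' @export
run_agd <- function(objective, nch, n_bins = 110L,
                    nfb_candidates = c(1L, 3L, 7L), rounds = 2L, top_m = 2L,
                    tol_pct = 1.0, params = searchable_params,
                    verbose = FALSE) {
  cache <- new.env(parent = emptyenv())
  eval_combo <- function(row) {
    key <- paste(row$nfb, row$nk1, row$nk2, row$k2, row$s2, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    hp <- hyperparam_set(row$nfb, row$nk1, row$nk2, row$k2, row$s2)
    perf <- objective(hp)
    res <- c(test_acc = as.numeric(perf[["test_acc"]]),
             train_acc = as.numeric(perf[["train_acc"]] %||% NA_real_),
             loss = as.numeric(perf[["loss"]] %||% NA_real_))
    cache[[key]] <- res
    res
  }
  eval_round <- function(combos) {
    perf <- t(vapply(seq_len(nrow(combos)),
                     function(i) eval_combo(combos[i, ]), numeric(3)))
    dplyr::bind_cols(combos, tibble::as_tibble(perf))
  }

  grid0 <- init_grids(nch, nfb_candidates, n_bins)
  combos <- enumerate_round(grid0)
  results <- eval_round(combos)
  seeds <- select_seed_sets(results, top_m)
  state_rounds <- list(list(grids = list(grid0), results = results,
                            seeds = seeds, trends = NULL))
  best_by_round <- max(results$test_acc)
  prev_trends <- NULL
  stopped <- FALSE

  for (r in seq_len(rounds)) {
    grids_r <- list()
    trends_r <- list()
    combo_list <- list()
    for (si in seq_len(nrow(seeds))) {
      seed_row <- seeds[si, ]
      prev_grid <- state_rounds[[length(state_rounds)]]$grids[[
        min(si, length(state_rounds[[length(state_rounds)]]$grids))]]
      new_grids <- list(nfb = seed_row$nfb)
      tr_seed <- list()
      for (p in params) {
        values <- sort(unique(prev_grid$grids[[p]]))
        if (length(values) < 3L) {        # frozen hyperparameter
          new_grids[[p]] <- values
          next
        }
        tr <- tryCatch(
          marginal_trend(state_rounds[[length(state_rounds)]]$results,
                         p, seed_row, values = values),
          error = function(e) NULL)
        if (is.null(tr)) {              # marginal combos not all evaluated
          new_grids[[p]] <- values
          next
        }
        tr_seed[[p]] <- as.character(tr)
        is_ratio <- p == "s2" && isTRUE(prev_grid$s2_is_ratio)
        upper <- if (p == "k2") {
          2L * n_bins * seed_row$nfb
        } else if (p == "s2") {
          if (is_ratio) 1 else max(new_grids$k2 %||% prev_grid$grids$k2)
        }
        new_grids[[p]] <- next_grid(values, tr,
                                    prev_trend = prev_trends[[si]][[p]],
                                    upper = upper, integer = !is_ratio)
      }
      for (nm in setdiff(c("nfb", "nk1", "nk2", "k2", "s2"),
                         names(new_grids))) {
        new_grids[[nm]] <- if (nm == "s2" && isTRUE(prev_grid$s2_is_ratio)) {
          seed_row$s2_ratio
        } else {
          seed_row[[nm]]
        }
      }
      g <- structure(list(grids = new_grids[c("nfb", "nk1", "nk2", "k2", "s2")],
                          round = r, nch = nch, n_bins = n_bins,
                          s2_is_ratio = isTRUE(prev_grid$s2_is_ratio)),
                     class = "agd_grid")
      grids_r[[si]] <- g
      trends_r[[si]] <- tr_seed
      combo_list[[si]] <- enumerate_round(g)
    }
    combos <- dplyr::distinct(dplyr::bind_rows(combo_list))
    results <- eval_round(combos)
    seeds <- select_seed_sets(results, top_m)
    state_rounds[[r + 1L]] <- list(grids = grids_r, results = results,
                                   seeds = seeds, trends = trends_r)
    best_by_round <- c(best_by_round, max(results$test_acc))
    prev_trends <- trends_r
    if (verbose) {
      message(sprintf("round %d: best test acc %.2f", r,
                      max(results$test_acc)))
    }
    if (should_stop(best_by_round, tol_pct)) {
      stopped <- TRUE
      break
    }
  }

  all_results <- dplyr::bind_rows(lapply(state_rounds, function(s) s$results))
  best <- select_seed_sets(all_results, 1L)
  structure(
    list(rounds = state_rounds, best_by_round = best_by_round,
         stopped_early = stopped, best = best, nch = nch, n_bins = n_bins),
    class = "agd_state"
  )
}

#' @export
print.agd_state <- function(x, ...) {
  cat(sprintf("<agd_state> %d round(s), best test acc per round: %s\n",
              length(x$rounds),
              paste(sprintf("%.2f", x$best_by_round), collapse = " -> ")))
  print(x$best)
  invisible(x)
}

#' @rdname run_agd
#' @param x An `agd_state`.
#' @export
tidy.agd_state <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$rounds), function(r) {
    dplyr::mutate(x$rounds[[r]]$results, round = r - 1L, .before = 1L)
  }))
}

#' @rdname run_agd
#' @export
glance.agd_state <- function(x, ...) {
  tibble::tibble(rounds = length(x$rounds),
                 n_evaluated = nrow(tidy(x)),
                 best_test_acc = max(x$best_by_round),
                 stopped_early = x$stopped_early)
}
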