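#' Target coverage contribution (TCC) component selection
#'
#' Orders active components by their cumulative coverage of a universe of
#' effective proteins. Target sets are intersected with the universe before
#' selection; components whose intersection is empty can never be picked.
#'
#' `mode = "greedy"` repeatedly picks the component with the largest marginal
#' coverage of still-uncovered effective proteins, stopping when coverage
#' stops increasing. Ties are broken by the larger total effective-target
#' count, then by the lexicographically smaller component id, so the
#' selection is deterministic. `mode = "exact"` (instances of at most 20
#' components) additionally computes, for each selection size `k`, the best
#' achievable coverage over all size-`k` subsets by exhaustive search; it is
#' intended as a small-instance oracle and reports the optimal coverage curve
#' in `cumulative_coverage` (the `order` column then lists a greedy ordering
#' of one optimal minimum-size subset achieving the maximum coverage).
#'
#' @param component_targets named list: component id -> character vector of
#'   target gene symbols.
#' @param effective nonempty character vector: the effective-protein universe.
#' @param mode `"greedy"` or `"exact"`.
#' @return object of class `tcc_selection`: list with `order` (picked
#'   component ids), `target_counts` (effective-target count per picked
#'   component), `marginal` (list of newly covered proteins per pick),
#'   `cumulative_coverage` (fraction of the universe covered after each
#'   pick), `universe`, `mode`, and for exact mode `optimal_by_k`.
#' @examples
#' sel <- tcc_select(list(c1 = c("p1", "p2", "p3"), c2 = c("p3", "p4"),
#'                        c3 = "p4"), effective = paste0("p", 1:4))
#' sel$order                 # c1 then c2
#' sel$cumulative_coverage   # 0.75 1.00
#' @export
tcc_select <- function(component_targets, effective, mode = c("greedy", "exact")) {
  mode <- match.arg(mode)
  effective <- unique(as.character(effective))
  if (!length(effective)) stop("effective-protein universe is empty")
  if (!length(component_targets)) {
    return(structure(list(order = character(), target_counts = integer(),
                          marginal = list(), cumulative_coverage = numeric(),
                          universe = effective, mode = mode),
                     class = "tcc_selection"))
  }
  if (is.null(names(component_targets)) || any(!nzchar(names(component_targets)))) {
    stop("component_targets must be a named list")
  }
  sets <- lapply(component_targets, function(s) intersect(unique(s), effective))
  total <- lengths(sets)

  # deterministic greedy: marginal gain, then total count, then id
  ids <- names(sets)
  uncovered <- effective
  order_ids <- character(); marginal <- list(); cum <- numeric()
  remaining <- ids
  while (length(remaining)) {
    gain <- vapply(sets[remaining], function(s) length(intersect(s, uncovered)), 0L)
    if (max(gain) == 0L) break
    cand <- remaining[gain == max(gain)]
    cand <- cand[order(-total[cand], cand)]
    pick <- cand[1]
    newly <- intersect(sets[[pick]], uncovered)
    order_ids <- c(order_ids, pick)
    marginal <- c(marginal, list(sort(newly)))
    uncovered <- setdiff(uncovered, newly)
    cum <- c(cum, (length(effective) - length(uncovered)) / length(effective))
    remaining <- setdiff(remaining, pick)
  }
  out <- list(order = order_ids, target_counts = total[order_ids],
              marginal = marginal, cumulative_coverage = cum,
              universe = effective, mode = mode)

  if (mode == "exact") {
    if (length(sets) > 20L) stop("exact mode is limited to 20 components")
    out$optimal_by_k <- tcc_exact_optimum(sets, effective)
    out$cumulative_coverage <- out$optimal_by_k$coverage
    out$order <- tcc_exact_order(sets, effective, out$optimal_by_k)
    out$target_counts <- total[out$order]
    out$marginal <- NULL
  }
  structure(out, class = "tcc_selection")
}

# exhaustive best coverage for every subset size k, via bitmask enumeration
tcc_exact_optimum <- function(sets, effective) {
  m <- length(sets)
  u <- length(effective)
  if (u > 31L) stop("exact mode requires an effective universe of at most 31 proteins")
  masks <- vapply(sets, function(s) {
    if (!length(s)) 0L else as.integer(sum(2^(match(s, effective) - 1L)))
  }, 0L)
  n_sub <- bitwShiftL(1L, m)
  orval <- integer(n_sub)
  size <- integer(n_sub)
  for (s in seq_len(n_sub - 1L)) {
    low <- bitwAnd(s, -s)
    prev <- bitwAnd(s, s - 1L)
    orval[s + 1L] <- bitwOr(orval[prev + 1L], masks[as.integer(round(log2(low))) + 1L])
    size[s + 1L] <- size[prev + 1L] + 1L
  }
  cov <- popcount32(orval)
  best <- vapply(seq_len(m), function(k) max(cov[size == k]), 0L)
  # max over size-k subsets is nondecreasing in k; cummax guards rounding
  best <- cummax(best)
  list(k = seq_len(m), covered = best, coverage = best / u)
}

popcount32 <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

# greedy ordering of one optimal minimum-size subset attaining max coverage
tcc_exact_order <- function(sets, effective, opt) {
  kstar <- which(opt$covered == max(opt$covered))[1]
  m <- length(sets)
  u <- length(effective)
  combos <- utils::combn(names(sets), kstar, simplify = FALSE)
  covered <- vapply(combos, function(ids) length(unique(unlist(sets[ids]))), 0L)
  best <- combos[[which(covered == max(covered))[1]]]
  sub <- tcc_select(sets[best], effective, mode = "greedy")
  sub$order
}

#' @export
print.tcc_selection <- function(x, ...) {
  cat("tcc_selection (", x$mode, "): ", length(x$order), " component(s), ",
      "final coverage ",
      if (length(x$cumulative_coverage))
        sprintf("%.2f%%", 100 * max(x$cumulative_coverage)) else "0.00%",
      " of ", length(x$universe), " effective proteins\n", sep = "")
  invisible(x)
}

#' @export
summary.tcc_selection <- function(object, ...) coverage_curve(object)

#' @export
plot.tcc_selection <- function(x, ...) {
  if (!length(x$order)) {
    graphics::plot.new(); graphics::title("empty TCC selection"); return(invisible(x))
  }
  graphics::plot(seq_along(x$cumulative_coverage), 100 * x$cumulative_coverage,
                 type = "s", xlab = "components selected",
                 ylab = "cumulative coverage (%)", ylim = c(0, 100),
                 main = "Accumulative target coverage contribution", ...)
  graphics::abline(h = 100, lty = 3)
  invisible(x)
}

#' Coverage curve of a TCC selection
#'
#' @param sel a `tcc_selection` from [tcc_select()] (greedy mode).
#' @return data.frame with one row per pick: `rank`, `component`, `marginal`
#'   (newly covered effective proteins), `cumulative_percent` (2 decimals).
#' @export
coverage_curve <- function(sel) {
  stopifnot(inherits(sel, "tcc_selection"))
  if (!length(sel$order)) {
    return(data.frame(rank = integer(), component = character(),
                      marginal = integer(), cumulative_percent = numeric(),
                      stringsAsFactors = FALSE))
  }
  marg <- if (!is.null(sel$marginal)) lengths(sel$marginal) else {
    diff(c(0, sel$cumulative_coverage)) * length(sel$universe)
  }
  data.frame(
    rank = seq_along(sel$order),
    component = unname(sel$order),
    marginal = as.integer(round(marg)),
    cumulative_percent = round(100 * sel$cumulative_coverage, 2),
    stringsAsFactors = FALSE
  )
}

#' Core active component group at a coverage target
#'
#' Shortest prefix of the selection order whose cumulative coverage reaches
#' `coverage_target`; if the target is unreachable, the full order is
#' returned flagged as unreached.
#'
#' @param sel a `tcc_selection`.
#' @param coverage_target fraction in (0, 1].
#' @return list with `components` (ordered ids), `coverage` (fraction reached)
#'   and `reached` (logical).
#' @export
cacg_at <- function(sel, coverage_target = 1) {
  stopifnot(inherits(sel, "tcc_selection"),
            coverage_target > 0, coverage_target <= 1)
  cum <- sel$cumulative_coverage
  hit <- which(cum >= coverage_target - 1e-12)
  if (length(hit)) {
    k <- hit[1]
    list(components = sel$order[seq_len(k)], coverage = cum[k], reached = TRUE)
  } else {
    list(components = sel$order,
         coverage = if (length(cum)) cum[length(cum)] else 0,
         reached = FALSE)
  }
}
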