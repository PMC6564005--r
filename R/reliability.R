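#' Per-unit rated values under a round-combination strategy
#'
#' Krippendorff's alpha is computed over "values": what each rater is taken to
#' have said about a unit. The four strategies turn the two ranked annotation
#' rounds into values differently:
#' \describe{
#'   \item{`r1_only`}{the round-1 sequence alone (27 possible values);}
#'   \item{`ordered`}{the ordered pair (R1, R2), a value in the product space
#'     of paths, compared with [composite_difference_ordered()];}
#'   \item{`unordered`}{the same pair but aligned to maximize overlap, so
#'     swapped priorities agree; compared with
#'     [composite_difference_unordered()] (pair keys are canonicalized by
#'     sorting the two paths);}
#'   \item{`r_optimal`}{one sequence per rater — R1 or R2 — chosen per unit by
#'     [optimal_selection()] to minimize the total pairwise distance,
#'     mirroring the consensus-seeking practice of expert movement analysts.}
#' }
#' Raters lacking a round-2 record contribute (R1, R1) under the composite
#' strategies.
#'
#' @param ds an `annotation_dataset`.
#' @param strategy one of `"r1_only"`, `"ordered"`, `"unordered"`,
#'   `"r_optimal"`.
#' @param exhaustive_limit maximum number of raters with distinct rounds per
#'   unit for the exhaustive `r_optimal` search (default 25).
#' @return a list with `values` (named list: unit id -> character vector of
#'   value keys, one per contributing rater), `kind` (`"simple"` or the pair
#'   kind matching the strategy), and for `r_optimal` a `selection` data frame
#'   (unit, rater, chosen round, achieved total distance).
#' @export
unit_values <- function(ds, strategy = c("r1_only", "ordered", "unordered", "r_optimal"),
                        exhaustive_limit = 25L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(ds, "annotation_dataset"))
  rec <- ds$records
  unit_ids <- ds$units$unit_id
  r1 <- rec[rec$round == 1L, , drop = FALSE]
  r2 <- rec[rec$round == 2L, , drop = FALSE]
  key2 <- setNames(r2$answer_path, paste(r2$rater_id, r2$unit_id, sep = "\r"))

  values <- setNames(vector("list", length(unit_ids)), unit_ids)
  selection <- NULL
  sel_rows <- list()
  for (u in unit_ids) {
    ru <- r1[r1$unit_id == u, , drop = FALSE]
    if (nrow(ru) == 0L) { values[[u]] <- character(0); next }
    ord <- order(ru$rater_id, method = "radix")
    ru <- ru[ord, , drop = FALSE]
    p1 <- ru$answer_path
    p2 <- key2[paste(ru$rater_id, u, sep = "\r")]
    p2[is.na(p2)] <- p1[is.na(p2)]
    p2 <- unname(p2)
    values[[u]] <- switch(
      strategy,
      r1_only = p1,
      ordered = paste(p1, p2, sep = "::"),
      unordered = {
        lo <- p1 <= p2  # canonical order within pair; swapped pairs share a key
        paste(ifelse(lo, p1, p2), ifelse(lo, p2, p1), sep = "::")
      },
      r_optimal = {
        sel <- optimal_selection(p1, p2, exhaustive_limit = exhaustive_limit)
        sel_rows[[u]] <- data.frame(
          unit_id = u, rater_id = ru$rater_id, chosen_round = sel$choice,
          total_distance = sel$total, stringsAsFactors = FALSE
        )
        ifelse(sel$choice == 2L, p2, p1)
      }
    )
  }
  if (strategy == "r_optimal") {
    selection <- do.call(rbind, unname(sel_rows))
    rownames(selection) <- NULL
  }
  list(
    values = values,
    kind = switch(strategy, r1_only = "simple", r_optimal = "simple",
                  ordered = "ordered", unordered = "unordered"),
    selection = selection
  )
}

#' Exhaustive agreement-maximizing round selection for one unit
#'
#' Evaluates every way of taking, from each rater, either the round-1 or the
#' round-2 sequence, and returns a selection minimizing the sum of pairwise
#' path-overlap distances among the chosen sequences. The search is exhaustive
#' over the raters whose two rounds differ (identical rounds make the choice
#' immaterial, reported as round 1). Ties are broken by preferring round 1,
#' then earlier raters.
#'
#' @param r1,r2 character vectors of path strings: each rater's round-1 and
#'   round-2 sequences, in rater order.
#' @param d distance function between two path strings (default
#'   [sequence_difference()]).
#' @param exhaustive_limit maximum number of raters with distinct rounds;
#'   above it the search is refused (2^m selections; consider subsetting).
#' @return a list with `choice` (integer vector of 1s and 2s per rater),
#'   `total` (achieved sum of pairwise distances) and `n_free` (raters
#'   actually enumerated).
#' @export
optimal_selection <- function(r1, r2, d = sequence_difference,
                              exhaustive_limit = 25L) {
  r1 <- as.character(r1); r2 <- as.character(r2)
  if (length(r1) != length(r2)) stop("r1 and r2 must have one entry per rater")
  n_free <- sum(r1 != r2)
  if (n_free > exhaustive_limit) {
    stop("unit has ", n_free, " raters with distinct rounds, above the ",
         "exhaustive limit (", exhaustive_limit, "); consider a subset analysis")
  }
  seqs <- unique(c(r1, r2))
  dm <- if (identical(d, sequence_difference)) {
    strategy_distance_matrix(seqs, "simple")
  } else {
    distance_matrix(seqs, d)
  }
  res <- select_optimal_cpp(dm, match(r1, seqs) - 1L, match(r2, seqs) - 1L)
  list(choice = as.integer(res$choice), total = as.numeric(res$total),
       n_free = as.integer(res$n_free))
}

#' Build the coincidence matrix of pairable values
#'
#' Cross-tabulates, over all units with at least two contributing raters,
#' every within-unit ordered pair of values, each pair weighted by
#' \eqn{1/(m_u - 1)} where \eqn{m_u} is the number of values in the unit. The
#' matrix is symmetric, its entries sum to the total number of pairable
#' values \eqn{n}, and its row sums are the value marginals \eqn{n_c}.
#'
#' @param values_by_unit named list: unit id -> character vector of value keys.
#' @param inventory optional canonical value inventory; defaults to the sorted
#'   distinct values of the included units.
#' @return an object of class `coincidence_matrix` with elements `values`,
#'   `o` (the matrix), `n_c` (marginals), `n`, `n_units` (included) and
#'   `n_excluded` (units with fewer than two values).
#' @export
build_coincidence <- function(values_by_unit, inventory = NULL) {
  m_u <- lengths(values_by_unit)
  included <- m_u >= 2L
  if (!any(included)) stop("no unit has two or more pairable values")
  vals <- values_by_unit[included]
  if (is.null(inventory)) {
    inventory <- sort(unique(unlist(vals, use.names = FALSE)), method = "radix")
  }
  v <- length(inventory)
  o <- matrix(0, v, v, dimnames = list(inventory, inventory))
  for (uv in vals) {
    idx <- match(uv, inventory)
    if (anyNA(idx)) stop("unit value missing from the inventory: ",
                         uv[is.na(idx)][1])
    m <- length(uv)
    tab <- tabulate(idx, nbins = v)
    contrib <- outer(tab, tab)
    diag(contrib) <- tab * (tab - 1)
    o <- o + contrib / (m - 1)
  }
  n_c <- rowSums(o)
  n <- sum(n_c)
  stopifnot(abs(n - sum(m_u[included])) < 1e-8)
  structure(
    list(values = inventory, o = o, n_c = n_c, n = n,
         n_units = sum(included), n_excluded = sum(!included)),
    class = "coincidence_matrix"
  )
}

#' Krippendorff's alpha from a coincidence matrix and a distance matrix
#'
#' \deqn{\alpha = 1 - D_o / D_e}
#' with observed disagreement \eqn{D_o = \sum_{c,k} o_{ck}\,\delta(c,k)} and
#' expected disagreement \eqn{D_e = \sum_{c,k} n_c n_k \delta(c,k) / (n-1)}.
#' The metric \eqn{\delta} is plugged in as a full matrix over the value
#' inventory, so any distance — nominal 0/1 or the path-overlap difference —
#' yields a chance-corrected agreement on the same scale. The distance is used
#' directly (not squared): it is itself the declared difference measure.
#'
#' @param cm a `coincidence_matrix`.
#' @param dmat symmetric distance matrix indexed identically to `cm$values`.
#' @param strategy optional strategy label carried into the result.
#' @return an object of class `alpha_result`: `alpha`, `D_o`, `D_e`, `n`,
#'   `n_units`, `n_excluded`, `strategy`, and `degenerate` (`TRUE` when
#'   \eqn{D_e = 0}, i.e. all values identical, in which case alpha is
#'   reported as 1).
#' @export
krippendorff_alpha <- function(cm, dmat, strategy = NULL) {
  stopifnot(inherits(cm, "coincidence_matrix"))
  if (!is.matrix(dmat) || any(dim(dmat) != length(cm$values))) {
    stop("distance matrix must be square over the value inventory")
  }
  if (!is.null(dimnames(dmat)) &&
      !identical(rownames(dmat), cm$values)) {
    stop("distance matrix rows must be indexed like the value inventory")
  }
  D_o <- sum(cm$o * dmat)
  D_e <- sum(outer(cm$n_c, cm$n_c) * dmat) / (cm$n - 1)
  degenerate <- D_e <= .Machine$double.eps * cm$n
  alpha <- if (degenerate) 1 else 1 - D_o / D_e
  structure(
    list(alpha = alpha, D_o = D_o, D_e = D_e, n = cm$n,
         n_units = cm$n_units, n_excluded = cm$n_excluded,
         strategy = strategy, degenerate = degenerate),
    class = "alpha_result"
  )
}

#' Krippendorff's alpha for a dataset under a round-combination strategy
#'
#' Composes [unit_values()], [build_coincidence()] and
#' [krippendorff_alpha()] with the strategy-appropriate distance: the simple
#' path-overlap difference for `r1_only` and `r_optimal`, the concatenated
#' (order-dependent) composite for `ordered`, and the overlap-maximizing
#' (order-independent) composite for `unordered`.
#'
#' @inheritParams unit_values
#' @return an `alpha_result`.
#' @export
alpha_by_strategy <- function(ds, strategy = c("r1_only", "ordered", "unordered", "r_optimal"),
                              exhaustive_limit = 25L) {
  strategy <- match.arg(strategy)
  uv <- unit_values(ds, strategy, exhaustive_limit = exhaustive_limit)
  cm <- build_coincidence(uv$values)
  dmat <- strategy_distance_matrix(cm$values, uv$kind)
  krippendorff_alpha(cm, dmat, strategy = strategy)
}

#' Subset reliability by gesture or intended variation category
#'
#' Computes alpha independently on each unit subset (coincidences and
#' marginals rebuilt per subset), as in per-gesture and per-category
#' reliability tables.
#'
#' @inheritParams unit_values
#' @param by unit metadata column to group by: `"gesture"` or
#'   `"intended_category"`.
#' @return named list of `alpha_result`, one per group with at least one
#'   pairable unit; groups without pairable units are dropped with a message
#'   and listed in the `"omitted"` attribute.
#' @export
subset_alpha <- function(ds, by = c("gesture", "intended_category"),
                         strategy = c("r1_only", "ordered", "unordered", "r_optimal"),
                         exhaustive_limit = 25L) {
  by <- match.arg(by)
  strategy <- match.arg(strategy)
  groups <- sort(unique(ds$units[[by]]), method = "radix")
  out <- list()
  omitted <- character(0)
  for (g in groups) {
    sub <- filter_dataset(ds, ds$units$unit_id[ds$units[[by]] == g])
    res <- tryCatch(
      alpha_by_strategy(sub, strategy, exhaustive_limit = exhaustive_limit),
      error = function(e) NULL
    )
    if (is.null(res)) {
      omitted <- c(omitted, g)
      message("group '", g, "' has no pairable unit; omitted")
    } else {
      out[[g]] <- res
    }
  }
  attr(out, "omitted") <- omitted
  out
}

#' Individual similarity to the modal annotation
#'
#' For each unit, finds the round-1 sequence given most often (the modal
#' annotation) and scores every rater's round-1 sequence against it with the
#' overlap similarity. Modal ties are resolved deterministically: among tied
#' sequences, the one with the smallest mean path-overlap distance to all
#' sequences of the unit wins; remaining ties fall back to byte-order of the
#' path string.
#'
#' @param ds an `annotation_dataset`.
#' @return a list with `ratings` (data frame: `rater_id`, `unit_id`,
#'   `similarity`), `raters` (data frame: `rater_id`, `mean_similarity`,
#'   `n_units`) and `modal` (data frame: `unit_id`, `modal_path`).
#' @export
individual_similarity <- function(ds) {
  uv <- unit_values(ds, "r1_only")$values
  rec <- ds$records[ds$records$round == 1L, , drop = FALSE]
  rows <- list()
  modal <- list()
  for (u in names(uv)) {
    seqs <- uv[[u]]
    if (length(seqs) < 2L) next
    tab <- table(seqs)
    cands <- names(tab)[tab == max(tab)]
    if (length(cands) > 1L) {
      mean_d <- vapply(cands, function(cand) {
        mean(vapply(seqs, function(s) sequence_difference(cand, s), numeric(1)))
      }, numeric(1))
      cands <- cands[mean_d == min(mean_d)]
      cands <- sort(cands, method = "radix")
    }
    mode_seq <- cands[[1]]
    ru <- rec[rec$unit_id == u, , drop = FALSE]
    ru <- ru[order(ru$rater_id, method = "radix"), , drop = FALSE]
    rows[[u]] <- data.frame(
      rater_id = ru$rater_id, unit_id = u,
      similarity = vapply(ru$answer_path, function(s) similarity(mode_seq, s),
                          numeric(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
    modal[[u]] <- data.frame(unit_id = u, modal_path = mode_seq,
                             stringsAsFactors = FALSE)
  }
  ratings <- do.call(rbind, unname(rows))
  if (is.null(ratings)) stop("no unit has two or more round-1 ratings")
  rownames(ratings) <- NULL
  agg <- aggregate(similarity ~ rater_id, data = ratings, FUN = mean)
  nn <- aggregate(similarity ~ rater_id, data = ratings, FUN = length)
  raters <- data.frame(rater_id = agg$rater_id,
                       mean_similarity = agg$similarity,
                       n_units = nn$similarity,
                       stringsAsFactors = FALSE)
  raters <- raters[order(raters$rater_id, method = "radix"), , drop = FALSE]
  rownames(raters) <- NULL
  list(ratings = ratings,
       raters = raters,
       modal = { m <- do.call(rbind, unname(modal)); rownames(m) <- NULL; m })
}

#' @export
print.alpha_result <- function(x, ...) {
  cat("Krippendorff's alpha",
      if (!is.null(x$strategy)) paste0(" [", x$strategy, "]"), "\n", sep = "")
  cat(sprintf("  alpha = %.4f   (D_o = %.4f, D_e = %.4f)\n",
              x$alpha, x$D_o, x$D_e))
  cat(sprintf("  n = %g pairable values over %d units (%d excluded)\n",
              x$n, x$n_units, x$n_excluded))
  if (isTRUE(x$degenerate)) cat("  note: degenerate data (all values identical)\n")
  invisible(x)
}

#' @export
print.coincidence_matrix <- function(x, ...) {
  cat("<coincidence_matrix>  ", length(x$values), " values, n = ", x$n,
      ", units = ", x$n_units, " (+", x$n_excluded, " excluded)\n", sep = "")
  invisible(x)
}
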