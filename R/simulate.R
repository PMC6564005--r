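#' Inventory of stimulus variations by gesture
#'
#' The full design space of movement variations used to build stimulus sets:
#' 24 variations of the knocking gesture and 19 of the giving-directions
#' gesture, spread over the Effort, Phrasing, Shape and Space categories
#' (neutral executions are not variations and are listed separately by
#' [lma_unit_design()]). Labels are informal stimulus names; leaves are the
#' corresponding terminal annotations of the default graph.
#'
#' @param graph a `decision_graph` used to resolve labels to leaves.
#' @return data frame with columns `gesture`, `variation_label`, `category`,
#'   `leaf`.
#' @export
lma_variation_inventory <- function(graph = lma_graph()) {
  effort <- c("bound", "direct", "free", "light", "quick", "strong", "sustained")
  phrasing <- c("impactive", "impulsive", "swing")
  shape <- c("advancing", "enclosing", "opening", "retreating", "rising", "sinking")
  space_knock <- c("far reach", "mid reach", "near reach", "side-across",
                   "side-open", "backwards", "down", "up")
  space_dir <- c("down", "mid reach", "near reach")
  one <- function(gesture, labels, category) {
    data.frame(gesture = gesture, variation_label = labels,
               category = category, leaf = resolve_alias(graph, labels),
               stringsAsFactors = FALSE)
  }
  rbind(
    one("knocking", effort, "Effort"),
    one("knocking", phrasing, "Phrasing"),
    one("knocking", shape, "Shape"),
    one("knocking", space_knock, "Space"),
    one("direction", effort, "Effort"),
    one("direction", phrasing, "Phrasing"),
    one("direction", shape, "Shape"),
    one("direction", space_dir, "Space")
  )
}

# largest-remainder apportionment of n slots across category counts
apportion <- function(counts, n) {
  q <- n * counts / sum(counts)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- q - base
    ord <- order(-frac, names(counts), method = "radix")
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Default unit design: the rated stimulus set
#'
#' Builds the per-rater set of rated units: by default 12 knocking and 10
#' giving-directions video pairs, each comprising one neutral execution
#' (intended category `Neutral`, leaf `NoChange`) and variations apportioned
#' across the four coding categories proportionally to the gesture's
#' variation inventory (largest-remainder rounding; knocking gets 3 Effort,
#' 1 Phrasing, 3 Shape, 4 Space; direction 3 Effort, 2 Phrasing, 3 Shape,
#' 1 Space). Within a category, variations are taken in alphabetical order
#' unless `seed` is given, in which case they are sampled.
#'
#' @param n_knocking,n_direction units per gesture (defaults 12 and 10,
#'   together the 22 pairs each rater annotates).
#' @param seed optional integer; sample variations instead of taking the
#'   alphabetically first ones.
#' @param graph a `decision_graph`.
#' @return data frame of unit metadata: `unit_id`, `gesture`,
#'   `variation_label`, `intended_category`, `intended_leaf`.
#' @export
lma_unit_design <- function(n_knocking = 12L, n_direction = 10L, seed = NULL,
                            graph = lma_graph()) {
  inv <- lma_variation_inventory(graph)
  with_seed(seed, {
    pick_gesture <- function(gesture, n, prefix) {
      stopifnot(n >= 1L)
      gi <- inv[inv$gesture == gesture, , drop = FALSE]
      counts <- table(gi$category)
      take <- apportion(setNames(as.numeric(counts), names(counts)), n - 1L)
      rows <- list(data.frame(gesture = gesture, variation_label = "neutral",
                              category = "Neutral", leaf = "NoChange",
                              stringsAsFactors = FALSE))
      for (cat in sort(names(take), method = "radix")) {
        ci <- gi[gi$category == cat, , drop = FALSE]
        ci <- ci[order(ci$variation_label, method = "radix"), , drop = FALSE]
        k <- take[[cat]]
        if (k > nrow(ci)) stop("category '", cat, "' has only ", nrow(ci),
                               " variations for gesture '", gesture, "'")
        idx <- if (is.null(seed)) seq_len(k) else sort(sample.int(nrow(ci), k))
        rows[[length(rows) + 1L]] <- ci[idx, c("gesture", "variation_label",
                                               "category", "leaf")]
      }
      out <- do.call(rbind, rows)
      out$unit_id <- sprintf("%s%02d", prefix, seq_len(nrow(out)))
      out
    }
    des <- rbind(pick_gesture("knocking", n_knocking, "K"),
                 pick_gesture("direction", n_direction, "D"))
    data.frame(unit_id = des$unit_id, gesture = des$gesture,
               variation_label = des$variation_label,
               intended_category = des$category,
               intended_leaf = des$leaf, stringsAsFactors = FALSE)
  })
}

#' Configuration for the rater-noise simulator
#'
#' The generative model behind synthetic annotation datasets. Per rater and
#' unit, the round-1 annotation equals the unit's intended leaf with
#' probability `1 - eps1`; otherwise a confusion is drawn — with probability
#' `lambda` a different leaf of the same category (qualitative
#' within-category confusion), else uniformly over all other leaves. Round 2
#' targets the unit's secondary truth (defaulting to the primary) with error
#' `eps2`, and with probability `pi_swap` the two rounds are exchanged,
#' modelling raters who prioritize the two observed changes differently.
#' Per-category error overrides let specific categories (e.g. the more
#' qualitative Effort and Shape judgements) be noisier. Viewing counts are
#' drawn per answered question from a lognormal model with a per-rater
#' propensity multiplier and per-gesture, per-round mean levels; they do not
#' influence the simulated answers.
#'
#' @param n_raters number of raters (default 18).
#' @param units unit design data frame as from [lma_unit_design()].
#' @param eps1,eps2 round-1 and round-2 error probabilities (defaults 0.4 and
#'   0.5).
#' @param lambda probability that a confusion stays within the true leaf's
#'   category (default 0.6).
#' @param pi_swap probability of swapping the two rounds (default 0.3).
#' @param category_error optional named numeric vector overriding the error
#'   rate (both rounds) per intended category, e.g.
#'   `c(Effort = 0.55, Shape = 0.55)`: lets specific categories be coded more
#'   noisily than others.
#' @param secondary_truth optional named character vector (unit id -> leaf)
#'   giving a distinct second true change per unit.
#' @param view_mean named numeric vector of mean views per question by
#'   gesture and round: `knocking_r1`, `knocking_r2`, `direction_r1`,
#'   `direction_r2`.
#' @param rater_view_sd standard deviation (log scale) of the per-rater
#'   viewing propensity multiplier.
#' @param question_view_sd lognormal sigma of per-question viewing counts.
#' @param seed integer seed making the simulated dataset fully reproducible.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_raters = 18L,
                              units = lma_unit_design(),
                              eps1 = 0.4, eps2 = 0.5,
                              lambda = 0.6, pi_swap = 0.3,
                              category_error = NULL,
                              secondary_truth = NULL,
                              view_mean = c(knocking_r1 = 5.3, knocking_r2 = 7.6,
                                            direction_r1 = 2.9, direction_r2 = 4.2),
                              rater_view_sd = 0.35,
                              question_view_sd = 0.45,
                              seed = NULL) {
  probs <- c(eps1 = eps1, eps2 = eps2, lambda = lambda, pi_swap = pi_swap,
             category_error)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  need <- c("knocking_r1", "knocking_r2", "direction_r1", "direction_r2")
  if (!all(need %in% names(view_mean)) || any(view_mean[need] <= 0)) {
    stop("view_mean must name positive means for ", paste(need, collapse = ", "))
  }
  if (n_raters < 1L) stop("need at least one rater")
  structure(
    list(n_raters = as.integer(n_raters), units = units,
         eps1 = eps1, eps2 = eps2, lambda = lambda, pi_swap = pi_swap,
         category_error = category_error, secondary_truth = secondary_truth,
         view_mean = view_mean, rater_view_sd = rater_view_sd,
         question_view_sd = question_view_sd, seed = seed),
    class = "simulation_config"
  )
}

#' Simulate a multi-rater annotation dataset
#'
#' Draws a complete dataset — every rater annotates every unit in both rounds
#' — under the noise model described in [simulation_config()]. Identical
#' seeds give bit-identical datasets after serialization.
#'
#' @param cfg a `simulation_config`.
#' @param graph a `decision_graph`; unit designs must cite its leaves.
#' @return an `annotation_dataset`.
#' @export
simulate_dataset <- function(cfg, graph = lma_graph()) {
  stopifnot(inherits(cfg, "simulation_config"))
  leaves <- enumerate_paths(graph)
  lp <- setNames(leaves$path, leaves$leaf)
  lcat <- setNames(leaves$category, leaves$leaf)
  units <- cfg$units
  bad <- !units$intended_leaf %in% names(lp)
  if (any(bad)) {
    stop("unit design cites leaf '", units$intended_leaf[bad][1],
         "' absent from graph '", graph$id, "'")
  }
  if (!is.null(cfg$secondary_truth)) {
    bad2 <- !cfg$secondary_truth %in% names(lp)
    if (any(bad2)) stop("secondary truth cites unknown leaf '",
                        cfg$secondary_truth[bad2][1], "'")
  }

  draw_leaf <- function(truth, eps) {
    if (runif(1) >= eps) return(truth)
    same <- setdiff(names(lp)[lcat == lcat[[truth]]], truth)
    if (length(same) && runif(1) < cfg$lambda) {
      sample(same, 1L)
    } else {
      sample(setdiff(names(lp), truth), 1L)
    }
  }

  with_seed(cfg$seed, {
    raters <- sprintf("R%02d", seq_len(cfg$n_raters))
    rater_mult <- exp(rnorm(cfg$n_raters, 0, cfg$rater_view_sd))
    qsd <- cfg$question_view_sd
    rows <- vector("list", cfg$n_raters * nrow(units) * 2L)
    k <- 0L
    for (ri in seq_along(raters)) {
      for (ui in seq_len(nrow(units))) {
        u <- units[ui, ]
        override <- !is.null(cfg$category_error) &&
          u$intended_category %in% names(cfg$category_error)
        eps1 <- if (override) cfg$category_error[[u$intended_category]] else cfg$eps1
        eps2 <- if (override) cfg$category_error[[u$intended_category]] else cfg$eps2
        truth2 <- if (!is.null(cfg$secondary_truth) &&
                      u$unit_id %in% names(cfg$secondary_truth)) {
          cfg$secondary_truth[[u$unit_id]]
        } else u$intended_leaf
        l1 <- draw_leaf(u$intended_leaf, eps1)
        l2 <- draw_leaf(truth2, eps2)
        if (runif(1) < cfg$pi_swap) { tmp <- l1; l1 <- l2; l2 <- tmp }
        for (rd in 1:2) {
          leaf <- if (rd == 1L) l1 else l2
          path <- lp[[leaf]]
          nq <- length(split_path(path))
          mu <- cfg$view_mean[[paste0(u$gesture, "_r", rd)]] * rater_mult[[ri]]
          views <- pmax(1L, as.integer(round(
            exp(rnorm(nq, log(mu) - qsd^2 / 2, qsd))
          )))
          k <- k + 1L
          rows[[k]] <- list(rater_id = raters[[ri]], unit_id = u$unit_id,
                            round = rd, answer_path = path,
                            views = paste(views, collapse = "|"))
        }
      }
    }
    records <- data.frame(
      rater_id = vapply(rows, `[[`, character(1), "rater_id"),
      unit_id = vapply(rows, `[[`, character(1), "unit_id"),
      round = vapply(rows, `[[`, integer(1), "round"),
      answer_path = vapply(rows, `[[`, character(1), "answer_path"),
      views = vapply(rows, `[[`, character(1), "views"),
      stringsAsFactors = FALSE
    )
    annotation_dataset(records,
                       units[c("unit_id", "gesture", "variation_label",
                               "intended_category", "intended_leaf")],
                       graph)
  })
}

#' Alpha recovery curve over a grid of error rates
#'
#' Replicated simulation harness: for each error rate in `epsilons`,
#' simulates `n_replicates` datasets and averages Krippendorff's alpha per
#' strategy. The grid rate is applied to both annotation rounds, so the
#' zero-error row is genuinely noise-free under every combination strategy
#' (priority swaps of two correct rounds are harmless). Deterministic given
#' `seed` (per-cell seeds are pre-drawn from it).
#'
#' @param epsilons numeric vector of error rates, applied to both rounds.
#' @param n_replicates replicates per error rate (default 100).
#' @param seed integer master seed.
#' @param cfg base `simulation_config`; its `eps1`, `eps2` and `seed` are
#'   overridden.
#' @param strategies strategies to evaluate (default `"r1_only"`).
#' @param graph a `decision_graph`.
#' @param file optional CSV path to write the curve to.
#' @return data frame with columns `eps1`, `strategy`, `mean_alpha`,
#'   `n_replicates`.
#' @export
recovery_curve <- function(epsilons = seq(0, 0.5, by = 0.1),
                           n_replicates = 100L, seed = 1L,
                           cfg = simulation_config(),
                           strategies = "r1_only",
                           graph = lma_graph(), file = NULL) {
  cell_seeds <- with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, length(epsilons) * n_replicates),
    nrow = length(epsilons)
  ))
  out <- list()
  for (ei in seq_along(epsilons)) {
    alphas <- matrix(NA_real_, n_replicates, length(strategies),
                     dimnames = list(NULL, strategies))
    for (rep in seq_len(n_replicates)) {
      cfg_i <- cfg
      cfg_i$eps1 <- epsilons[[ei]]
      cfg_i$eps2 <- epsilons[[ei]]
      cfg_i$seed <- cell_seeds[ei, rep]
      ds <- simulate_dataset(cfg_i, graph)
      for (s in strategies) {
        alphas[rep, s] <- alpha_by_strategy(ds, s)$alpha
      }
    }
    out[[ei]] <- data.frame(eps1 = epsilons[[ei]], strategy = strategies,
                            mean_alpha = colMeans(alphas),
                            n_replicates = n_replicates,
                            stringsAsFactors = FALSE)
  }
  curve <- do.call(rbind, out)
  rownames(curve) <- NULL
  if (!is.null(file)) write.csv(curve, file, row.names = FALSE)
  curve
}
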