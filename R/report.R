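#' Viewing-behavior summary
#'
#' Descriptive and inferential statistics of how often raters replayed the
#' stimulus videos: per-rater per-gesture mean total views per stimulus
#' (summed over both rounds' questions) with a paired t-test across raters;
#' per-rater per-round mean views per question with a paired t-test; the
#' Pearson correlation between a rater's round-1 and round-2 viewing; and,
#' when per-rater similarity scores are supplied, the Pearson correlation
#' between mean similarity and mean viewing.
#'
#' Degenerate inputs (no variance anywhere) make a t statistic or a
#' correlation undefined; those entries are returned as `NA` with a `flag`
#' explaining why.
#'
#' @param ds an `annotation_dataset` with viewing counts.
#' @param similarity optional data frame with `rater_id` and
#'   `mean_similarity`, as in the `raters` element of
#'   [individual_similarity()].
#' @return a list of class `viewing_summary`: `per_rater_gesture`,
#'   `t_gesture`, `per_rater_round`, `t_round`, `cor_rounds`,
#'   `cor_similarity_views`.
#' @export
viewing_summary <- function(ds, similarity = NULL) {
  stopifnot(inherits(ds, "annotation_dataset"))
  rec <- ds$records
  if (nrow(rec) == 0L) stop("dataset has no records")
  view_list <- strsplit(rec$views, "|", fixed = TRUE)
  rec$total_views <- vapply(view_list, function(v) sum(as.integer(v)), numeric(1))
  rec$n_questions <- lengths(view_list)
  gesture <- setNames(ds$units$gesture, ds$units$unit_id)
  rec$gesture <- unname(gesture[rec$unit_id])

  # total views per (rater, unit), both rounds pooled -> mean per gesture
  per_unit <- aggregate(total_views ~ rater_id + unit_id + gesture, data = rec, FUN = sum)
  prg <- aggregate(total_views ~ rater_id + gesture, data = per_unit, FUN = mean)
  names(prg)[names(prg) == "total_views"] <- "mean_views_per_unit"
  prg <- prg[order(prg$rater_id, prg$gesture, method = "radix"), , drop = FALSE]
  rownames(prg) <- NULL

  t_gesture <- paired_block(prg, "gesture", "knocking", "direction",
                            "mean_views_per_unit")

  # mean views per question per (rater, round)
  pq <- aggregate(cbind(total_views, n_questions) ~ rater_id + round,
                  data = rec, FUN = sum)
  pq$mean_views_per_question <- pq$total_views / pq$n_questions
  prr <- pq[c("rater_id", "round", "mean_views_per_question")]
  prr <- prr[order(prr$rater_id, prr$round, method = "radix"), , drop = FALSE]
  rownames(prr) <- NULL
  prr$round <- as.integer(prr$round)

  t_round <- paired_block(transform(prr, round = paste0("r", round)),
                          "round", "r1", "r2", "mean_views_per_question")

  cor_rounds <- cor_block(
    wide_pairs(transform(prr, round = paste0("r", round)),
               "round", "r1", "r2", "mean_views_per_question")
  )

  cor_sim <- NULL
  if (!is.null(similarity)) {
    views_rater <- aggregate(total_views ~ rater_id, data = per_unit, FUN = mean)
    names(views_rater)[2] <- "mean_views"
    merged <- merge(similarity[c("rater_id", "mean_similarity")], views_rater,
                    by = "rater_id")
    cor_sim <- cor_block(merged[c("mean_similarity", "mean_views")])
  }

  structure(
    list(per_rater_gesture = prg, t_gesture = t_gesture,
         per_rater_round = prr, t_round = t_round,
         cor_rounds = cor_rounds, cor_similarity_views = cor_sim),
    class = "viewing_summary"
  )
}

# paired t-test block on a long data frame; x/y are levels of `col`
paired_block <- function(df, col, level_x, level_y, value) {
  wide <- wide_pairs(df, col, level_x, level_y, value)
  out <- list(
    mean_x = mean(wide[[1]]), sd_x = sd(wide[[1]]),
    mean_y = mean(wide[[2]]), sd_y = sd(wide[[2]]),
    levels = c(level_x, level_y),
    n = nrow(wide), t = NA_real_, df = NA_real_, p = NA_real_, flag = NULL
  )
  diffs <- wide[[1]] - wide[[2]]
  if (nrow(wide) < 2L || sd(diffs) == 0) {
    out$flag <- "t statistic undefined: fewer than 2 pairs or zero-variance differences"
    if (nrow(wide) >= 1L && all(diffs == 0)) out$t <- 0
    return(out)
  }
  tt <- t.test(wide[[1]], wide[[2]], paired = TRUE)
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p <- tt$p.value
  out
}

wide_pairs <- function(df, col, level_x, level_y, value) {
  x <- df[df[[col]] == level_x, c("rater_id", value)]
  y <- df[df[[col]] == level_y, c("rater_id", value)]
  m <- merge(x, y, by = "rater_id", suffixes = c("_x", "_y"))
  m[c(paste0(value, "_x"), paste0(value, "_y"))]
}

cor_block <- function(xy) {
  out <- list(r = NA_real_, p = NA_real_, n = nrow(xy), flag = NULL)
  if (nrow(xy) < 3L || sd(xy[[1]]) == 0 || sd(xy[[2]]) == 0) {
    out$flag <- "correlation undefined: fewer than 3 raters or zero variance"
    return(out)
  }
  ct <- cor.test(xy[[1]], xy[[2]])
  out$r <- unname(ct$estimate)
  out$p <- ct$p.value
  out
}

#' Run the full reliability analysis
#'
#' One call from a dataset (file or object) or a simulation configuration to
#' a machine-readable report: Krippendorff's alpha under each
#' round-combination strategy, per-gesture and per-category subset alphas,
#' per-rater similarity to the modal annotation, viewing-behavior statistics,
#' and provenance (input hash, graph id, seed, package version).
#'
#' @param data an `annotation_dataset`, a path to a dataset CSV, or `NULL`
#'   when `config` is given.
#' @param config optional `simulation_config`; when given, the dataset is
#'   simulated (with `seed` overriding the config's seed if supplied).
#' @param graph a `decision_graph`.
#' @param strategies strategies to compute overall alpha for.
#' @param subset_strategy strategy for the per-gesture and per-category
#'   tables (default `"r_optimal"`, the agreement-maximizing combination).
#' @param exhaustive_limit passed to the `r_optimal` search.
#' @param seed optional integer overriding the simulation seed.
#' @return an object of class `lma_report`.
#' @export
run_analysis <- function(data = NULL, config = NULL, graph = lma_graph(),
                         strategies = c("r1_only", "ordered", "unordered", "r_optimal"),
                         subset_strategy = "r_optimal",
                         exhaustive_limit = 25L, seed = NULL) {
  input_md5 <- NA_character_
  if (is.null(data) && is.null(config)) stop("supply a dataset or a simulation config")
  if (is.null(data)) {
    if (!is.null(seed)) config$seed <- seed
    if (is.null(config$seed)) stop("simulation input needs a seed for a reproducible report")
    ds <- simulate_dataset(config, graph)
    used_seed <- config$seed
  } else {
    if (is.character(data)) {
      input_md5 <- unname(tools::md5sum(data))
      ds <- read_dataset(data, graph)
    } else {
      ds <- data
      tmp <- tempfile(fileext = ".csv")
      on.exit(unlink(tmp), add = TRUE)
      write_dataset(ds, tmp)
      input_md5 <- unname(tools::md5sum(tmp))
    }
    used_seed <- seed
  }

  alphas <- lapply(setNames(strategies, strategies), function(s) {
    alpha_by_strategy(ds, s, exhaustive_limit = exhaustive_limit)
  })
  by_gesture <- subset_alpha(ds, "gesture", subset_strategy,
                             exhaustive_limit = exhaustive_limit)
  by_category <- subset_alpha(ds, "intended_category", subset_strategy,
                              exhaustive_limit = exhaustive_limit)
  sim <- individual_similarity(ds)
  viewing <- viewing_summary(ds, sim$raters)

  n_excl <- vapply(alphas, function(a) a$n_excluded, numeric(1))
  message("units included: ", alphas[[1]]$n_units, " (excluded: ",
          paste(sprintf("%s=%d", names(n_excl), as.integer(n_excl)), collapse = ", "), ")")

  structure(
    list(
      strategies = alphas,
      by_gesture = by_gesture,
      by_category = by_category,
      similarity = sim,
      viewing = viewing,
      provenance = list(
        package = "lmarel",
        version = as.character(utils::packageVersion("lmarel")),
        schema = "lma-report/1",
        graph_id = graph$id,
        seed = used_seed,
        input_md5 = input_md5,
        n_raters = length(ds$raters),
        n_units = nrow(ds$units),
        n_records = nrow(ds$records)
      )
    ),
    class = "lma_report"
  )
}

#' Write an analysis report to JSON (and optional CSV tables)
#'
#' @param report an `lma_report`.
#' @param file path for the JSON report.
#' @param tables_dir optional directory for CSV tables (overall strategies,
#'   per-gesture, per-category, per-rater similarity), created if needed.
#' @return `file`, invisibly.
#' @export
write_report <- function(report, file, tables_dir = NULL) {
  stopifnot(inherits(report, "lma_report"))
  alpha_row <- function(a) {
    list(alpha = a$alpha, D_o = a$D_o, D_e = a$D_e, n = a$n,
         n_units = a$n_units, n_excluded = a$n_excluded,
         degenerate = a$degenerate)
  }
  payload <- list(
    schema = report$provenance$schema,
    provenance = report$provenance,
    strategies = lapply(report$strategies, alpha_row),
    by_gesture = lapply(report$by_gesture, alpha_row),
    by_category = lapply(report$by_category, alpha_row),
    similarity = list(per_rater = report$similarity$raters,
                      modal = report$similarity$modal),
    viewing = report$viewing[c("t_gesture", "t_round", "cor_rounds",
                               "cor_similarity_views")]
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(tables_dir)) {
    dir.create(tables_dir, showWarnings = FALSE, recursive = TRUE)
    alpha_table <- function(lst) {
      data.frame(group = names(lst),
                 alpha = vapply(lst, function(a) a$alpha, numeric(1)),
                 n = vapply(lst, function(a) a$n, numeric(1)),
                 n_units = vapply(lst, function(a) a$n_units, numeric(1)),
                 stringsAsFactors = FALSE)
    }
    write.csv(alpha_table(report$strategies),
              file.path(tables_dir, "alpha_by_strategy.csv"), row.names = FALSE)
    write.csv(alpha_table(report$by_gesture),
              file.path(tables_dir, "alpha_by_gesture.csv"), row.names = FALSE)
    write.csv(alpha_table(report$by_category),
              file.path(tables_dir, "alpha_by_category.csv"), row.names = FALSE)
    write.csv(report$similarity$raters,
              file.path(tables_dir, "rater_similarity.csv"), row.names = FALSE)
  }
  invisible(file)
}

#' @export
print.lma_report <- function(x, ...) {
  cat("<lma_report>  graph: ", x$provenance$graph_id,
      "   raters: ", x$provenance$n_raters,
      "   units: ", x$provenance$n_units, "\n", sep = "")
  cat("  alpha by strategy:\n")
  for (s in names(x$strategies)) {
    cat(sprintf("    %-10s %.3f\n", s, x$strategies[[s]]$alpha))
  }
  if (length(x$by_category)) {
    cat("  alpha by intended category (", x$by_category[[1]]$strategy, "):\n", sep = "")
    for (g in names(x$by_category)) {
      cat(sprintf("    %-10s %.3f\n", g, x$by_category[[g]]$alpha))
    }
  }
  invisible(x)
}
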