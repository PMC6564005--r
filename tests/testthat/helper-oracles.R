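# Independent oracles and fixture builders. Each oracle takes a different
# computational route from the implementation it checks.

# breadth-first path enumeration (implementation is depth-first)
oracle_paths <- function(graph) {
  res <- character(0)
  queue <- list(list(q = graph$root, toks = character(0)))
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    ans <- graph$questions[[cur$q]]$answers
    for (tok in names(ans)) {
      tgt <- ans[[tok]]
      if (is.character(tgt)) {
        queue[[length(queue) + 1L]] <- list(q = tgt, toks = c(cur$toks, tok))
      } else {
        res <- c(res, paste(c(cur$toks, tok), collapse = "|"))
      }
    }
  }
  sort(res, method = "radix")
}

# nominal Krippendorff's alpha straight from the per-unit pair-counting
# definition, with no coincidence matrix
oracle_nominal_alpha <- function(values_by_unit) {
  vals <- values_by_unit[lengths(values_by_unit) >= 2L]
  n <- sum(lengths(vals))
  do_sum <- 0
  for (v in vals) {
    m <- length(v)
    do_sum <- do_sum + sum(outer(v, v, "!=")) / (m - 1)
  }
  D_o <- do_sum / n
  nc <- table(unlist(vals))
  D_e <- (n^2 - sum(nc^2)) / (n * (n - 1))
  1 - D_o / D_e
}

# exhaustive round-selection by mask enumeration with a cached lookup table;
# rater 1 is the most significant bit so ascending masks are lexicographic
oracle_best_selection <- function(r1, r2, d = sequence_difference) {
  m <- length(r1)
  seqs <- unique(c(r1, r2))
  lut <- outer(seq_along(seqs), seq_along(seqs),
               Vectorize(function(i, j) d(seqs[[i]], seqs[[j]])))
  i1 <- match(r1, seqs); i2 <- match(r2, seqs)
  best <- Inf; best_choice <- NULL
  for (mask in 0:(2^m - 1)) {
    bits <- integer(m)
    for (i in seq_len(m)) bits[i] <- bitwAnd(bitwShiftR(mask, m - i), 1L)
    idx <- ifelse(bits == 1L, i2, i1)
    tot <- sum(lut[idx, idx][upper.tri(lut[idx, idx])])
    if (tot < best - 1e-12) {
      best <- tot
      best_choice <- bits + 1L
    }
  }
  list(choice = best_choice, total = best)
}

# five-leaf graph: one no-change path plus two categories of two leaves
mini_graph <- function() {
  load_graph(list(
    id = "mini",
    root = "q1",
    questions = list(
      q1 = list(prompt = "change?", answers = list(
        No = list(leaf = "NoChange", category = "NoChange"),
        Yes = "q2"
      )),
      q2 = list(prompt = "which?", answers = list(A = "qa", B = "qb")),
      qa = list(prompt = "a?", answers = list(
        A1 = list(leaf = "A1", category = "CatA"),
        A2 = list(leaf = "A2", category = "CatA")
      )),
      qb = list(prompt = "b?", answers = list(
        B1 = list(leaf = "B1", category = "CatB"),
        B2 = list(leaf = "B2", category = "CatB")
      ))
    )
  ))
}

# random rooted tree spec with bounded depth; leaf labels unique by counter
random_tree_spec <- function(seed, max_depth = 5L) {
  set.seed(seed)
  counter <- new.env()
  counter$q <- 0L
  counter$leaf <- 0L
  questions <- list()
  build <- function(depth) {
    counter$q <- counter$q + 1L
    qid <- paste0("q", counter$q)
    n_ans <- sample(2:3, 1)
    answers <- list()
    for (k in seq_len(n_ans)) {
      tok <- paste0("t", qid, "_", k)
      if (depth >= max_depth || runif(1) < 0.5) {
        counter$leaf <- counter$leaf + 1L
        answers[[tok]] <- list(leaf = paste0("L", counter$leaf), category = "C")
      } else {
        answers[[tok]] <- build(depth + 1L)
      }
    }
    questions[[qid]] <<- list(prompt = qid, answers = answers)
    qid
  }
  root <- build(1L)
  list(id = paste0("random-", seed), root = root, questions = questions)
}

# small annotation dataset from a list: unit -> rater -> c(r1, r2) or r1 only
fixture_dataset <- function(unit_raters, graph = lma_graph(),
                            gesture = "knocking") {
  rows <- list()
  for (u in names(unit_raters)) {
    for (r in names(unit_raters[[u]])) {
      paths <- unit_raters[[u]][[r]]
      for (rd in seq_along(paths)) {
        nq <- length(strsplit(paths[[rd]], "|", fixed = TRUE)[[1]])
        rows[[length(rows) + 1L]] <- data.frame(
          rater_id = r, unit_id = u, round = rd, answer_path = paths[[rd]],
          views = paste(rep(1L, nq), collapse = "|"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  records <- do.call(rbind, rows)
  units <- data.frame(
    unit_id = unique(names(unit_raters)),
    gesture = gesture,
    intended_category = "Neutral",
    intended_leaf = "NoChange",
    stringsAsFactors = FALSE
  )
  annotation_dataset(records, units, graph)
}

# random per-unit nominal value lists for alpha-oracle comparisons
random_values_by_unit <- function(seed) {
  set.seed(seed)
  n_units <- sample(3:8, 1)
  n_vals <- sample(2:5, 1)
  domain <- letters[seq_len(n_vals)]
  out <- list()
  for (u in seq_len(n_units)) {
    m <- sample(2:6, 1)
    out[[paste0("u", u)]] <- sample(domain, m, replace = TRUE)
  }
  out
}
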