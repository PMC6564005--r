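#' Load and validate a decision-graph specification
#'
#' A decision graph formalizes a hierarchical coding scheme: internal nodes are
#' multiple-choice questions, edges are answer tokens, and terminal edges carry
#' a leaf annotation label plus the coding category it belongs to. An
#' annotation is the ordered sequence of answers on one root-to-leaf path.
#'
#' The specification is a JSON document (or an equivalent R list) of the form
#' `{id, root, questions: {qid: {prompt, answers: {token: next-qid |
#' {leaf, category}}}}, aliases: {label: leaf}}`. Validation enforces that the
#' graph is a rooted DAG, that every question is reachable from the root, that
#' answer tokens are unique within a question, and that leaf labels are unique
#' across the graph.
#'
#' @param spec path to a JSON graph specification, or a list with elements
#'   `root`, `questions` and optionally `id`, `aliases`.
#' @return an object of class `decision_graph`.
#' @examples
#' g <- lma_graph()
#' nrow(enumerate_paths(g))  # 27
#' @export
load_graph <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    if (!file.exists(spec)) stop("graph specification file not found: ", spec)
    spec <- jsonlite::read_json(spec, simplifyVector = FALSE)
  }
  if (!is.list(spec)) stop("graph specification must be a file path or a list")
  for (field in c("root", "questions")) {
    if (is.null(spec[[field]])) stop("graph specification lacks '", field, "'")
  }
  questions <- spec$questions
  qids <- names(questions)
  if (is.null(qids) || anyDuplicated(qids)) {
    stop("question ids must be unique and named")
  }
  root <- as.character(spec$root)
  if (!root %in% qids) stop("root question '", root, "' is not declared")

  for (qid in qids) {
    ans <- questions[[qid]]$answers
    if (is.null(ans) || length(ans) == 0L) {
      stop("question '", qid, "' declares no answers")
    }
    toks <- names(ans)
    if (is.null(toks) || any(toks == "") || anyDuplicated(toks)) {
      stop("question '", qid, "' has missing or duplicate answer tokens")
    }
    for (tok in toks) {
      tgt <- ans[[tok]]
      if (is.character(tgt)) {
        if (!tgt %in% qids) {
          stop("answer '", tok, "' of question '", qid,
               "' points to undeclared question '", tgt, "'")
        }
      } else if (is.list(tgt)) {
        if (is.null(tgt$leaf) || is.null(tgt$category)) {
          stop("leaf answer '", tok, "' of question '", qid,
               "' must declare both 'leaf' and 'category'")
        }
      } else {
        stop("answer '", tok, "' of question '", qid,
             "' must be a question id or a leaf object")
      }
    }
  }

  # iterative DFS: detects cycles (grey node re-entered) and reachability
  state <- setNames(rep(0L, length(qids)), qids)  # 0 white, 1 grey, 2 black
  visit <- function(qid) {
    if (state[[qid]] == 1L) stop("cycle detected through question '", qid, "'")
    if (state[[qid]] == 2L) return(invisible())
    state[qid] <<- 1L
    for (tgt in questions[[qid]]$answers) {
      if (is.character(tgt)) visit(tgt)
    }
    state[qid] <<- 2L
    invisible()
  }
  visit(root)
  unreachable <- qids[state == 0L]
  if (length(unreachable)) {
    stop("questions not reachable from root: ",
         paste(unreachable, collapse = ", "))
  }

  g <- structure(
    list(
      id = spec$id %||% "custom",
      root = root,
      questions = questions,
      aliases = vapply(spec$aliases %||% list(), as.character, character(1))
    ),
    class = "decision_graph"
  )
  leaves <- enumerate_paths(g)
  if (anyDuplicated(leaves$leaf)) {
    stop("leaf labels are not unique: ",
         paste(unique(leaves$leaf[duplicated(leaves$leaf)]), collapse = ", "))
  }
  g
}

#' The packaged LMA decision graph
#'
#' Loads the default coding graph for movement-change annotation: a root
#' change/no-change question, a category question (Effort, Space, Shape,
#' Phrasing), and element questions per category, giving 27 terminal
#' annotations. In the untrimmed graph the Space branch is one question deeper
#' (the "where does the change in Space occur" question splitting kinesphere
#' zone from reach), so Space paths take four answers while all other change
#' paths take three. With `trimmed = TRUE` (the default, and the form used in
#' all reliability computations) that intermediate answer is contracted via
#' [trim_equalize()] so that every change path has exactly three answers; the
#' no-change path keeps length one.
#'
#' @param trimmed contract the Space branch so all change paths have equal
#'   length (default `TRUE`).
#' @return a `decision_graph`.
#' @export
lma_graph <- function(trimmed = TRUE) {
  g <- load_graph(system.file("extdata", "lma_graph.json", package = "lmarel",
                              mustWork = TRUE))
  if (trimmed) {
    g <- trim_equalize(g, list(c("Space", "q_space_where")))
    g$id <- paste0(g$id, "-trimmed")
  }
  g
}

#' Contract answers to equalize path lengths
#'
#' For each `(answer-token, question-id)` pair, removes the named answer and
#' the question it points to, re-attaching that question's answers directly to
#' the parent question. This shortens all paths through the contracted answer
#' by one position while leaving the set of leaves unchanged; it is the
#' "trimming" step that gives all change annotations equal path length so that
#' the positional overlap difference treats every branch alike.
#'
#' @param graph a `decision_graph`.
#' @param contracted list of length-2 character vectors
#'   `c(answer_token, question_id)`: the answer to remove and the question it
#'   leads to (whose answers are promoted).
#' @return the contracted `decision_graph`.
#' @export
trim_equalize <- function(graph, contracted) {
  stopifnot(inherits(graph, "decision_graph"))
  if (length(contracted) == 0L) return(graph)
  n_before <- nrow(enumerate_paths(graph))
  spec <- unclass(graph)
  for (ct in contracted) {
    if (length(ct) != 2L) stop("each contraction must be c(answer_token, question_id)")
    tok <- ct[[1]]; qid <- ct[[2]]
    if (!qid %in% names(spec$questions)) {
      stop("contraction target question '", qid, "' does not exist")
    }
    parent <- NULL
    for (p in names(spec$questions)) {
      ans <- spec$questions[[p]]$answers
      tgt <- ans[[tok]]
      if (!is.null(tgt) && is.character(tgt) && tgt == qid) { parent <- p; break }
    }
    if (is.null(parent)) {
      # the answer token may exist but point at a leaf: nothing to contract
      for (p in names(spec$questions)) {
        tgt <- spec$questions[[p]]$answers[[tok]]
        if (!is.null(tgt) && is.list(tgt)) {
          stop("answer '", tok, "' is a leaf; nothing to contract")
        }
      }
      stop("no question has answer '", tok, "' leading to '", qid, "'")
    }
    promoted <- spec$questions[[qid]]$answers
    pans <- spec$questions[[parent]]$answers
    pans[[tok]] <- NULL
    clash <- intersect(names(promoted), names(pans))
    if (length(clash)) {
      stop("contraction would duplicate answer tokens: ",
           paste(clash, collapse = ", "))
    }
    spec$questions[[parent]]$answers <- c(pans, promoted)
    spec$questions[[qid]] <- NULL
  }
  out <- load_graph(spec)
  n_after <- nrow(enumerate_paths(out))
  if (n_after != n_before) {
    stop("internal error: contraction changed leaf count (", n_before,
         " -> ", n_after, ")")
  }
  out
}

#' Enumerate all legal annotation paths
#'
#' Depth-first traversal with answer tokens visited in byte-order, so the
#' result is deterministic across platforms and runs.
#'
#' @param graph a `decision_graph`.
#' @return a data frame with one row per root-to-leaf path: `path` (answer
#'   tokens joined by `"|"`), `leaf`, `category`, and `length` (number of
#'   answers).
#' @export
enumerate_paths <- function(graph) {
  questions <- graph$questions
  acc <- vector("list", 0L)
  walk <- function(qid, tokens) {
    ans <- questions[[qid]]$answers
    for (tok in sort(names(ans), method = "radix")) {
      tgt <- ans[[tok]]
      if (is.character(tgt)) {
        walk(tgt, c(tokens, tok))
      } else {
        acc[[length(acc) + 1L]] <<- list(
          path = paste(c(tokens, tok), collapse = "|"),
          leaf = as.character(tgt$leaf),
          category = as.character(tgt$category),
          length = length(tokens) + 1L
        )
      }
    }
  }
  walk(graph$root, character())
  data.frame(
    path = vapply(acc, `[[`, character(1), "path"),
    leaf = vapply(acc, `[[`, character(1), "leaf"),
    category = vapply(acc, `[[`, character(1), "category"),
    length = vapply(acc, `[[`, integer(1), "length"),
    stringsAsFactors = FALSE
  )
}

#' Validate an answer sequence against a graph
#'
#' Walks the sequence of answer tokens from the root; errors if at any point
#' the token is not a legal answer of the current question, or if the sequence
#' stops before a leaf or continues past one.
#'
#' @param graph a `decision_graph`.
#' @param tokens character vector of answer tokens, or a single `"|"`-joined
#'   path string.
#' @return a list with `leaf`, `category` and `path` (the canonical path
#'   string), invisibly usable as confirmation of legality.
#' @export
validate_sequence <- function(graph, tokens) {
  tokens <- split_path(tokens)
  if (length(tokens) == 0L) stop("empty answer sequence")
  qid <- graph$root
  leafinfo <- NULL
  for (i in seq_along(tokens)) {
    if (is.null(qid)) {
      stop("sequence continues past a terminal annotation: ",
           paste(tokens, collapse = "|"))
    }
    tgt <- graph$questions[[qid]]$answers[[tokens[[i]]]]
    if (is.null(tgt)) {
      stop("'", tokens[[i]], "' is not a legal answer of question '", qid,
           "' (sequence ", paste(tokens, collapse = "|"), ")")
    }
    qid <- if (is.character(tgt)) tgt else NULL
    leafinfo <- if (is.list(tgt)) tgt else NULL
  }
  if (!is.null(qid)) {
    stop("sequence stops at question '", qid, "' before reaching a leaf: ",
         paste(tokens, collapse = "|"))
  }
  list(leaf = as.character(leafinfo$leaf),
       category = as.character(leafinfo$category),
       path = paste(tokens, collapse = "|"))
}

#' Resolve a stimulus label to a leaf annotation
#'
#' Stimulus design tables use informal labels (e.g. `"opening"`, `"near
#' reach"`); the graph's alias table maps them onto leaf labels
#' (`"Spreading"`, `"Near"`). Labels that already are leaves pass through.
#'
#' @param graph a `decision_graph`.
#' @param label character vector of labels.
#' @return character vector of leaf labels.
#' @export
resolve_alias <- function(graph, label) {
  leaves <- enumerate_paths(graph)$leaf
  out <- vapply(as.character(label), function(lb) {
    if (lb %in% leaves) return(lb)
    hit <- unname(graph$aliases[tolower(lb)])
    if (is.na(hit) || !hit %in% leaves) {
      stop("label '", lb, "' resolves to no leaf of graph '", graph$id, "'")
    }
    hit
  }, character(1))
  unname(out)
}

# path string <-> token vector
split_path <- function(x) {
  if (length(x) == 1L && is.character(x)) {
    strsplit(x, "|", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
}

# leaf label -> canonical path string, for the whole graph
leaf_paths <- function(graph) {
  p <- enumerate_paths(graph)
  setNames(p$path, p$leaf)
}

#' @export
print.decision_graph <- function(x, ...) {
  p <- enumerate_paths(x)
  cat("<decision_graph '", x$id, "'>\n", sep = "")
  cat("  questions: ", length(x$questions),
      "   terminal annotations: ", nrow(p), "\n", sep = "")
  cat("  path lengths: ", paste(sort(unique(p$length)), collapse = ", "),
      "\n", sep = "")
  cat("  categories: ",
      paste(sort(unique(p$category)), collapse = ", "), "\n", sep = "")
  invisible(x)
}
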