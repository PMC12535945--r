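#' Candidate hypotheses: sets of gene-function facts
#'
#' A hypothesis is a set of ground abducible facts `function(gene,
#' reaction)`, each asserting that a gene catalyses a (masked) reaction.
#' Its size is the number of facts; the empty hypothesis (size 0) is a
#' legal member of the hypothesis space and predicts no catalysis for any
#' masked reaction.
#'
#' @param genes,reactions parallel character vectors: fact k is
#'   `function(genes[k], reactions[k])`. Both empty for the empty
#'   hypothesis.
#' @param id stable identifier; derived from the facts when omitted.
#' @return an object of class `hypothesis`.
#' @export
hypothesis <- function(genes = character(), reactions = character(),
                       id = NULL) {
  genes <- as.character(genes)
  reactions <- as.character(reactions)
  stopifnot(length(genes) == length(reactions))
  ord <- order(reactions, genes)
  facts <- data.frame(gene = genes[ord], reaction = reactions[ord],
                      stringsAsFactors = FALSE)
  facts <- unique(facts)
  if (is.null(id)) {
    id <- if (nrow(facts) == 0L) {
      "empty"
    } else {
      paste(paste0(facts$gene, ":", facts$reaction), collapse = "+")
    }
  }
  structure(list(id = id, facts = facts), class = "hypothesis")
}

#' @rdname hypothesis
#' @param h a `hypothesis`.
#' @export
hypothesis_size <- function(h) {
  stopifnot(inherits(h, "hypothesis"))
  nrow(h$facts)
}

#' @export
print.hypothesis <- function(x, ...) {
  if (hypothesis_size(x) == 0L) {
    cat("<hypothesis> empty\n")
  } else {
    cat("<hypothesis>", x$id, "\n")
  }
  invisible(x)
}

#' @export
format.hypothesis <- function(x, ...) x$id

#' Positive-prediction and false-positive counts for a hypothesis
#'
#' `pc` counts positive predictions over *all* candidate experiments
#' (labelled and unlabelled) — generality is estimated on the whole
#' instance pool. `fp` counts labelled negatives that the hypothesis
#' predicts positive.
#'
#' @param pred_row 0/1 prediction vector over the full experiment list.
#' @param labels named integer vector of labels in \{0, 1\}, names are
#'   indices (or names matching `pred_row` names) of labelled
#'   experiments; may be empty.
#' @return list with integer fields `pc` and `fp`.
#' @export
coverage_counts <- function(pred_row, labels = integer()) {
  pred_row <- as_bool(pred_row)
  pc <- sum(pred_row)
  fp <- 0L
  if (length(labels) > 0L) {
    if (is.null(names(labels))) {
      stop("labels must be named by experiment", call. = FALSE)
    }
    idx <- if (!is.null(names(pred_row))) {
      match(names(labels), names(pred_row))
    } else {
      suppressWarnings(as.integer(names(labels)))
    }
    if (anyNA(idx) || any(idx < 1L) || any(idx > length(pred_row))) {
      stop("label refers to unknown experiment", call. = FALSE)
    }
    fp <- sum(labels == 0L & pred_row[idx] == 1L)
  }
  list(pc = as.integer(pc), fp = as.integer(fp))
}

#' MDL compression score of a hypothesis
#'
#' `compression = n_pos - (n_pos / pc) * (size + fp)` where `n_pos` is
#' the number of positive labelled examples seen so far, `pc` the
#' positive-prediction count and `fp` the false-positive count of the
#' hypothesis. Compact hypotheses that cover many positives and few
#' labelled negatives compress best. Degenerate cases: with no positive
#' examples every hypothesis scores 0; a hypothesis with `pc = 0` while
#' positives exist explains nothing and scores `-Inf` (posterior mass 0).
#'
#' @param size number of facts in the hypothesis.
#' @param n_pos number of positive labelled examples.
#' @param pc,fp counts from [coverage_counts()].
#' @return a real (possibly `-Inf`).
#' @export
compression <- function(size, n_pos, pc, fp) {
  stopifnot(length(size) == 1L, length(n_pos) == 1L,
            length(pc) == 1L, length(fp) == 1L)
  if (size < 0 || n_pos < 0 || pc < 0 || fp < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (n_pos == 0) return(0)
  if (pc == 0) return(-Inf)
  n_pos - (n_pos / pc) * (size + fp)
}

#' Description-length prior of a hypothesis
#'
#' `p(h) = 2^(-size(h))`: each fact costs one bit. Provided for
#' completeness; the selection loop ranks hypotheses by compression,
#' which already embeds the size penalty.
#'
#' @param size number of facts (vectorised).
#' @return numeric prior weights.
#' @export
prior <- function(size) {
  stopifnot(all(size >= 0))
  2^(-size)
}

#' Normalised posterior from compression scores
#'
#' Softmax in base 2 over the version space:
#' `p'(h | E) = 2^compression(h) / sum_i 2^compression(h_i)`, computed
#' with a max shift for numerical stability. `-Inf` compressions get
#' posterior 0.
#'
#' @param compressions numeric vector, at least one finite entry.
#' @return numeric vector summing to 1.
#' @export
posterior <- function(compressions) {
  stopifnot(length(compressions) >= 1L)
  if (all(is.infinite(compressions) & compressions < 0)) {
    stop("empty effective version space: all compressions are -Inf",
         call. = FALSE)
  }
  m <- max(compressions)
  w <- 2^(compressions - m)
  w[is.nan(w)] <- 0  # -Inf - m
  w / sum(w)
}

#' Shannon entropy (bits) of a posterior subset
#'
#' `J = -sum p log2 p` with `0 log2 0 = 0`. The input posteriors are
#' taken as-is — a strict subset of the version space is *not*
#' renormalised, following the literal reading of the selection
#' heuristic.
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @return entropy in bits.
#' @export
entropy_term <- function(p) {
  if (any(p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(p) == 0L) return(0)
  terms <- ifelse(p > 0, -p * log2(p), 0)
  sum(terms)
}

#' Tabulate scores for a hypothesis space
#'
#' Builds the per-hypothesis score table (size, pc, fp, compression,
#' posterior) for a prediction matrix and a set of labels. Exported as
#' the score-table surface of the scoring module.
#'
#' @param H list of [hypothesis()] objects.
#' @param pred 0/1 prediction matrix, rows aligned with `H`, columns =
#'   all candidate experiments.
#' @param labels named integer vector of labels (names = experiment
#'   column names or indices).
#' @param alive optional logical vector restricting the version space;
#'   posteriors are computed over the alive subset (dead rows get NA).
#' @return data.frame with columns hypothesis_id, size, pc, fp,
#'   compression, posterior.
#' @export
score_table <- function(H, pred, labels = integer(),
                        alive = rep(TRUE, length(H))) {
  stopifnot(length(H) == nrow(pred), length(alive) == length(H))
  n_pos <- if (length(labels) > 0L) sum(labels == 1L) else 0L
  sizes <- vapply(H, hypothesis_size, integer(1L))
  pcfp <- lapply(seq_along(H), function(i) coverage_counts(pred[i, ], labels))
  pc <- vapply(pcfp, `[[`, integer(1L), "pc")
  fp <- vapply(pcfp, `[[`, integer(1L), "fp")
  comp <- vapply(seq_along(H), function(i) {
    compression(sizes[[i]], n_pos, pc[[i]], fp[[i]])
  }, numeric(1L))
  post <- rep(NA_real_, length(H))
  if (any(alive)) post[alive] <- posterior(comp[alive])
  data.frame(
    hypothesis_id = vapply(H, `[[`, character(1L), "id"),
    size = sizes, pc = pc, fp = fp,
    compression = comp, posterior = post,
    stringsAsFactors = FALSE
  )
}
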