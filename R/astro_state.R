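## Four-signature reactive-state scoring of astrocyte expression profiles:
## per-sample mean z-scores over the A1 (inflammatory), A2 (alternative),
## fetal (progenitor) and adult (mature) signature sets, projected onto a
## differentiation axis (fetal - adult) and a reactivity axis (A2 - A1).

.STATE_NAMES <- c("A1", "A2", "fetal", "adult")

#' Load the four astrocyte state signatures from a GMT file
#'
#' The file must contain sets named exactly `A1`, `A2`, `fetal` and `adult`
#' (additional sets are ignored with a message). The pairwise overlap matrix
#' is attached for inspection; the published signature lists are not
#' bundled — see [synthetic_state_signatures()] for the clearly labeled
#' synthetic stand-in used by the examples and tests.
#'
#' @param path GMT file path.
#' @return object of class `state_signatures`: named list of the four gene
#'   sets, with attributes `overlap` (4 x 4 matrix of shared gene counts)
#'   and `provenance` (the file path).
#' @export
load_signatures <- function(path) {
  coll <- read_gmt(path)
  missing <- setdiff(.STATE_NAMES, names(coll))
  if (length(missing))
    stop("signature set(s) missing from GMT: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(coll), .STATE_NAMES)
  if (length(extra))
    log_msg("astro_state", "ignoring %d extra set(s): %s",
            length(extra), paste(extra, collapse = ", "))
  sets <- coll[.STATE_NAMES]
  ov <- vapply(sets, function(a)
    vapply(sets, function(b) length(intersect(a, b)), integer(1)),
    integer(4))
  structure(sets, overlap = ov, provenance = path,
            class = "state_signatures")
}

#' Synthetic astrocyte state signatures (fixture)
#'
#' Four disjoint synthetic gene sets named after the reactive states. These
#' are placeholders with the size and structure of the published top-50
#' signature lists, for testing and simulation only — they carry no
#' biological meaning and never stand in for the published gene lists on
#' real data. The same sets ship as
#' `inst/extdata/synthetic_state_signatures.gmt`.
#'
#' @param n_genes genes per set (default 50).
#' @param gene_pool optional character vector to draw the genes from
#'   (first `4 * n_genes` used, in order); default synthetic IDs.
#' @return a `state_signatures` object with provenance
#'   `"synthetic-fixture"`.
#' @export
synthetic_state_signatures <- function(n_genes = 50, gene_pool = NULL) {
  if (is.null(gene_pool))
    gene_pool <- sprintf("SYN%04d", seq_len(4 * n_genes))
  if (length(gene_pool) < 4 * n_genes)
    stop("gene_pool must contain at least ", 4 * n_genes, " genes")
  sets <- split(gene_pool[seq_len(4 * n_genes)],
                rep(.STATE_NAMES, each = n_genes))[.STATE_NAMES]
  ov <- vapply(sets, function(a)
    vapply(sets, function(b) length(intersect(a, b)), integer(1)),
    integer(4))
  structure(sets, overlap = ov, provenance = "synthetic-fixture",
            class = "state_signatures")
}

#' Per-sample signature scores
#'
#' Expression is z-scored per gene across samples (a zero-variance gene
#' contributes z = 0), then each state's score is the mean z over the set's
#' genes present in the matrix. Raw means (no z-scoring) are available for
#' sensitivity analysis but are dominated by high-abundance genes. A set
#' intersecting fewer than `min_genes` matrix genes yields flagged scores.
#'
#' @param expr genes x samples log-scale expression matrix (e.g. from
#'   [normalize_log()]).
#' @param sigs a `state_signatures` object.
#' @param min_genes minimum genes present per set for an unflagged score
#'   (default 10).
#' @param z_score z-score genes before averaging (default TRUE).
#' @return object of class `signature_scores`: `data.frame` with columns
#'   `sample`, `score_A1`, `score_A2`, `score_fetal`, `score_adult`;
#'   attributes `n_genes_used` (per set) and `flagged` (per set).
#' @export
score_states <- function(expr, sigs, min_genes = 10, z_score = TRUE) {
  stopifnot(inherits(sigs, "state_signatures"))
  expr <- as.matrix(expr)
  z <- if (z_score) {
    mu <- rowMeans(expr)
    sdv <- apply(expr, 1, stats::sd)
    zz <- (expr - mu) / ifelse(sdv == 0, 1, sdv)
    zz[sdv == 0, ] <- 0
    zz
  } else expr
  n_used <- integer(4); names(n_used) <- .STATE_NAMES
  scores <- matrix(NA_real_, ncol(expr), 4,
                   dimnames = list(colnames(expr), .STATE_NAMES))
  for (st in .STATE_NAMES) {
    present <- intersect(sigs[[st]], rownames(z))
    if (!length(present))
      stop("signature '", st, "' shares no genes with the matrix")
    n_used[st] <- length(present)
    scores[, st] <- colMeans(z[present, , drop = FALSE])
  }
  flagged <- n_used < min_genes
  out <- data.frame(sample = colnames(expr),
                    score_A1 = scores[, "A1"], score_A2 = scores[, "A2"],
                    score_fetal = scores[, "fetal"],
                    score_adult = scores[, "adult"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, n_genes_used = n_used, flagged = flagged,
            class = c("signature_scores", "data.frame"))
}

#' Differentiation / reactivity coordinates and state labels
#'
#' The two axes of the state map: `x = score_fetal - score_adult` (positive
#' towards the progenitor side) and `y = score_A2 - score_A1` (positive
#' towards alternative reactivity). The label is the axis of maximum
#' absolute coordinate mapped to its sign — progenitor (`x > 0`), mature
#' (`x < 0`), alternative (`y > 0`), inflammatory (`y < 0`) — when that
#' maximum reaches `margin` (in z units); otherwise `unclassified`. On the
#' exact tie `|x| == |y|` the differentiation axis wins.
#'
#' @param scores a `signature_scores` object with no flagged sets.
#' @param margin classification margin in z units (default 0.25).
#' @return `data.frame` of class `state_coordinates`: columns `sample`, `x`,
#'   `y`, `state`.
#' @export
state_coordinates <- function(scores, margin = 0.25) {
  stopifnot(inherits(scores, "signature_scores"))
  fl <- attr(scores, "flagged")
  if (any(fl))
    stop("flagged signature score(s) (", paste(names(fl)[fl], collapse = ", "),
         " below min_genes); coordinates would be unreliable")
  x <- scores$score_fetal - scores$score_adult
  y <- scores$score_A2 - scores$score_A1
  state <- ifelse(pmax(abs(x), abs(y)) < margin, "unclassified",
           ifelse(abs(x) >= abs(y),
                  ifelse(x > 0, "progenitor", "mature"),
                  ifelse(y > 0, "alternative", "inflammatory")))
  out <- data.frame(sample = scores$sample, x = x, y = y, state = state,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("state_coordinates", "data.frame")
  out
}

#' Per-cohort summary of the state map
#'
#' Centroid coordinates, coordinate dispersions and per-state counts per
#' cohort — the table behind cohort-level state-shift scatterplots.
#'
#' @param coords a `state_coordinates` table (or rbind of several).
#' @param cohort per-sample cohort labels aligned with `coords` rows.
#' @return `data.frame`: one row per cohort with `n`, `centroid_x`,
#'   `centroid_y`, `sd_x`, `sd_y` and one `n_<state>` count column per state
#'   label; counts per row sum to the cohort size.
#' @export
state_report <- function(coords, cohort) {
  stopifnot(inherits(coords, "state_coordinates"))
  cohort <- as.character(cohort)
  if (length(cohort) != nrow(coords))
    stop("cohort must have one label per sample")
  if (!nrow(coords)) stop("empty cohort table")
  states <- c("mature", "progenitor", "inflammatory", "alternative",
              "unclassified")
  rows <- lapply(unique(cohort), function(ch) {
    sub <- coords[cohort == ch, ]
    cnt <- vapply(states, function(s) sum(sub$state == s), integer(1))
    df <- data.frame(cohort = ch, n = nrow(sub),
                     centroid_x = mean(sub$x), centroid_y = mean(sub$y),
                     sd_x = if (nrow(sub) > 1) stats::sd(sub$x) else 0,
                     sd_y = if (nrow(sub) > 1) stats::sd(sub$y) else 0,
                     stringsAsFactors = FALSE)
    for (s in states) df[[paste0("n_", s)]] <- cnt[[s]]
    df
  })
  do.call(rbind, rows)
}
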