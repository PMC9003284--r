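# EDAS (Evaluation based on Distance from Average Solution) multi-criteria
# ranking. Alternatives are scored by their positive / negative distances
# from the per-criterion mean (PDA / NDA), weight-summed (SP / SN),
# normalized (NSP / NSN) and combined into an appraisal score in [0,1].
#
# Two sign conventions are supported. The published worked example this
# package reproduces computes, for a beneficial criterion,
#   PDA = max(0, (mean - x) / mean),  NDA = max(0, (x - mean) / mean)
# i.e. it *rewards falling below the average* — the opposite of textbook
# EDAS. `convention = "as_printed"` (default) reproduces that instance
# cell-for-cell; `convention = "standard"` is the textbook method. Pick
# "standard" for any new analysis.

#' Construct a decision matrix
#'
#' @param values numeric matrix, alternatives x criteria.
#' @param alternatives,criteria name vectors; taken from dimnames when
#'   omitted.
#' @param weights per-criterion non-negative weights; normalized warning-
#'   free, they are used as given (the worked example's weights sum to
#'   1.0001).
#' @param beneficial logical per criterion, `TRUE` = larger is better.
#' @return object of class `decision_matrix`.
#' @export
decision_matrix <- function(values, alternatives = rownames(values),
                            criteria = colnames(values),
                            weights = rep(1 / ncol(values), ncol(values)),
                            beneficial = rep(TRUE, ncol(values))) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("matrix must be finite", call. = FALSE)
  if (length(weights) != ncol(values))
    stop("one weight per criterion required", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (is.null(alternatives)) alternatives <- paste0("A", seq_len(nrow(values)))
  if (is.null(criteria)) criteria <- paste0("C", seq_len(ncol(values)))
  dimnames(values) <- list(alternatives, criteria)
  structure(list(values = values, weights = as.numeric(weights),
                 beneficial = as.logical(beneficial)),
            class = "decision_matrix")
}

#' Read a decision matrix from CSV
#'
#' Layout: header row of criterion names, first column alternative names,
#' optional row named `weights` carrying the criterion weights.
#'
#' @param path CSV file.
#' @param weights overrides any weights row.
#' @param beneficial per-criterion flags.
#' @return a [decision_matrix()].
#' @export
read_decision_matrix <- function(path, weights = NULL, beneficial = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  alts <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  wrow <- tolower(alts) == "weights"
  if (any(wrow)) {
    if (is.null(weights)) weights <- as.numeric(vals[wrow, ])
    vals <- vals[!wrow, , drop = FALSE]
    alts <- alts[!wrow]
  }
  if (is.null(weights)) weights <- rep(1 / ncol(vals), ncol(vals))
  if (is.null(beneficial)) beneficial <- rep(TRUE, ncol(vals))
  decision_matrix(vals, alts, colnames(vals), weights, beneficial)
}

#' The packaged defocus-method benchmark decision matrix
#'
#' The published performance table (Precision, Recall, F1-score of ten
#' defocus-segmentation methods) that the ranking worked example starts
#' from, with its exogenous criterion weights (0.6125, 0.2737, 0.1139).
#'
#' @return a [decision_matrix()].
#' @export
blur_benchmark_matrix <- function() {
  path <- system.file("extdata", "defocus_methods_scores.csv",
                      package = "focusfield", mustWork = TRUE)
  read_decision_matrix(path)
}

#' Rank alternatives with EDAS
#'
#' Runs steps 1-8: criterion means, PDA/NDA matrices, weighted sums SP/SN,
#' normalized scores NSP = SP/max(SP) and NSN = 1 - SN/max(SN), appraisal
#' `(NSP + NSN)/2`, and a descending ranking (stable ties by input order).
#' Degenerate normalizations: all SP = 0 gives NSP = 0 for everyone, all
#' SN = 0 gives NSN = 1, so an all-identical matrix scores 0.5 throughout.
#'
#' @param dm a [decision_matrix()].
#' @param convention `"as_printed"` (reproduces the published worked
#'   example; see the note in this file) or `"standard"` (textbook EDAS).
#' @return object of class `edas_result`: list with `means`, `pda`, `nda`,
#'   `sp`, `sn`, `nsp`, `nsn`, `appraisal`, `ranking` (rank per
#'   alternative) and `order` (alternative indices best-first).
#' @export
edas_rank <- function(dm, convention = c("as_printed", "standard")) {
  convention <- match.arg(convention)
  x <- dm$values
  means <- colMeans(x)
  if (any(means == 0))
    stop("zero criterion mean: PDA/NDA undefined", call. = FALSE)
  below <- sweep(-x, 2L, means, "+")   # mean - x
  below <- sweep(pmax(below, 0), 2L, means, "/")
  above <- sweep(x, 2L, -means, "+")   # x - mean
  above <- sweep(pmax(above, 0), 2L, means, "/")
  flip <- if (convention == "as_printed") dm$beneficial else !dm$beneficial
  pda <- nda <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  pda[, flip] <- below[, flip];   pda[, !flip] <- above[, !flip]
  nda[, flip] <- above[, flip];   nda[, !flip] <- below[, !flip]
  sp <- drop(pda %*% dm$weights)
  sn <- drop(nda %*% dm$weights)
  nsp <- if (max(sp) > 0) sp / max(sp) else rep(0, length(sp))
  nsn <- if (max(sn) > 0) 1 - sn / max(sn) else rep(1, length(sn))
  appraisal <- (nsp + nsn) / 2
  ord <- order(-appraisal, seq_along(appraisal))
  ranking <- integer(length(ord)); ranking[ord] <- seq_along(ord)
  names(sp) <- names(sn) <- names(nsp) <- names(nsn) <-
    names(appraisal) <- names(ranking) <- rownames(x)
  structure(list(means = means, pda = pda, nda = nda, sp = sp, sn = sn,
                 nsp = nsp, nsn = nsn, appraisal = appraisal,
                 ranking = ranking, order = ord, convention = convention),
            class = "edas_result")
}

#' @export
print.edas_result <- function(x, digits = 4, ...) {
  cat("EDAS ranking (", x$convention, " convention)\n\n", sep = "")
  tab <- data.frame(SP = x$sp, SN = x$sn, NSP = x$nsp, NSN = x$nsn,
                    appraisal = x$appraisal, rank = x$ranking)
  print(round(tab, digits))
  invisible(x)
}
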