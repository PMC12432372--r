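#' Encode lesion calls into the integer marker matrix
#'
#' Builds the samples x markers matrix of integer lesion scores used for
#' consensus clustering. The scoring tiers:
#'
#' * gene mutations — nonsilent or indel 2, synonymous 1, none 0;
#' * CNV gain peaks — copy number above 3.7 scores 2 (high-grade gain),
#'   within \[2.4, 3.7\] scores 1 (low-grade gain), otherwise 0; losses at a
#'   gain peak score 0;
#' * CNV loss peaks — copy number at or below 0.80 scores 2 (high-grade
#'   loss), within (0.80, 1.6\] scores 1 (low-grade loss), otherwise 0;
#'   gains at a loss peak score 0;
#' * SV markers — present 3, absent 0.
#'
#' Copy numbers in the neutral gap (1.6, 2.4) score 0 and are not an error;
#' negative copy numbers are. Absent (sample, marker) pairs score 0. The
#' encoding is a pure function of its inputs.
#'
#' @param calls lesion calls data.frame (`sample`, `marker`, `kind` in
#'   mutation/cnv/sv, `detail`: consequence class, absolute copy number, or
#'   0/1 flag).
#' @param markers data.frame with `marker` and `kind` (mutation,
#'   cnv_gain_peak, cnv_loss_peak, sv) defining columns and their direction.
#' @param samples optional sample ids fixing row order (default: those seen
#'   in `calls`).
#' @return integer matrix samples x markers, class `lesion_matrix`, with the
#'   marker kinds attached as attribute `marker_kind`.
#' @export
encode_lesions <- function(calls, markers, samples = NULL) {
  if (!all(calls$marker %in% markers$marker)) {
    stop("calls reference markers missing from the marker list: ",
         paste(utils::head(setdiff(calls$marker, markers$marker)),
               collapse = ", "))
  }
  if (is.null(samples)) samples <- sort(unique(calls$sample))
  m <- matrix(0L, length(samples), nrow(markers),
              dimnames = list(samples, markers$marker))
  kind_of <- stats::setNames(markers$kind, markers$marker)
  for (i in seq_len(nrow(calls))) {
    s <- calls$sample[i]; mk <- calls$marker[i]
    if (!s %in% samples) next
    mkind <- kind_of[[mk]]
    score <- switch(
      calls$kind[i],
      mutation = {
        if (mkind != "mutation") 0L else
          switch(calls$detail[i],
                 nonsilent = 2L, indel = 2L, synonymous = 1L, none = 0L,
                 stop("unknown mutation consequence: ", calls$detail[i]))
      },
      cnv = {
        cn <- as.numeric(calls$detail[i])
        if (is.na(cn)) stop("non-numeric copy number: ", calls$detail[i])
        if (cn < 0) stop("negative copy number at ", mk)
        if (mkind == "cnv_gain_peak") {
          if (cn > 3.7) 2L else if (cn >= 2.4) 1L else 0L
        } else if (mkind == "cnv_loss_peak") {
          if (cn <= 0.80) 2L else if (cn <= 1.6) 1L else 0L
        } else 0L
      },
      sv = {
        if (mkind != "sv") 0L else if (calls$detail[i] %in% c("1", "TRUE")) 3L
        else 0L
      },
      stop("unknown lesion kind: ", calls$kind[i]))
    m[s, mk] <- max(m[s, mk], score)
  }
  attr(m, "marker_kind") <- kind_of
  class(m) <- c("lesion_matrix", class(m))
  m
}

#' Cophenetic correlation of a consensus matrix
#'
#' Pearson correlation between the consensus dissimilarities `1 - C` and the
#' cophenetic distances of their average-linkage dendrogram. Values near 1
#' indicate that the consensus matrix is well described by a clean
#' hierarchical partition.
#'
#' @param consensus symmetric matrix with unit diagonal, entries in \[0, 1\].
#' @return correlation in \[-1, 1\]; `NA` when all off-diagonal
#'   dissimilarities are identical (flagged with a warning). A 2 x 2 matrix
#'   returns 1 by construction.
#' @export
cophenetic_coefficient <- function(consensus) {
  stopifnot(nrow(consensus) == ncol(consensus))
  d <- stats::as.dist(1 - consensus)
  if (length(d) == 1L) return(1)
  if (stats::sd(d) == 0) {
    warning("all consensus dissimilarities identical; cophenetic undefined")
    return(NA_real_)
  }
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  if (stats::sd(cd) == 0) return(NA_real_)
  stats::cor(d, cd)
}

#' NMF consensus clustering of a lesion matrix
#'
#' For each candidate K, runs `n_runs` Frobenius NMF factorizations of the
#' markers x samples matrix from seeded random starts; each run assigns every
#' sample to its maximum-loading factor. The consensus matrix holds the
#' fraction of runs in which each sample pair co-clusters. K is selected as
#' the argmax of the cophenetic coefficient over `k_range` (ties to the
#' smaller K); final labels cut the average-linkage dendrogram of
#' `1 - consensus` at the selected K.
#'
#' @param lesions a `lesion_matrix` (samples x markers) or any non-negative
#'   matrix with samples in rows.
#' @param k_range candidate cluster numbers (default 2:10).
#' @param n_runs NMF runs per K (>= 30; default 100).
#' @param seed master seed; per-run seeds derive from it deterministically.
#' @param max_iter,tol passed to [nmf_factorize()].
#' @return list with `consensus` (list of matrices by K), `cophenetic`
#'   (named numeric by K), `selected_k`, `labels` (integer vector named by
#'   sample), `zero_samples` (ids of all-zero rows, assigned by the
#'   hierarchical step and flagged here).
#' @export
nmf_consensus <- function(lesions, k_range = 2:10, n_runs = 100L, seed = 1L,
                          max_iter = 60L, tol = 1e-4) {
  X <- t(unclass(as.matrix(lesions)))   # markers x samples
  if (any(X < 0)) stop("lesion matrix must be non-negative")
  n <- ncol(X)
  if (stats::sd(as.numeric(X)) == 0) stop("degenerate input: constant matrix")
  if (n_runs < 30L) stop("n_runs must be >= 30")
  if (n < 2L * max(k_range)) {
    stop("need at least 2 x max(k_range) samples")
  }
  ks <- sort(unique(as.integer(k_range)))
  consensus <- list(); coph <- stats::setNames(numeric(length(ks)),
                                               as.character(ks))
  for (i in seq_along(ks)) {
    K <- ks[i]
    co <- matrix(0, n, n)
    for (r in seq_len(n_runs)) {
      fit <- nmf_factorize(X, K, objective = "frobenius",
                           max_iter = max_iter, tol = tol,
                           seed = .spawn_seed(seed, K * 100000L + r))
      lab <- max.col(t(fit$H), ties.method = "first")
      co <- co + outer(lab, lab, "==")
    }
    co <- co / n_runs
    diag(co) <- 1
    dimnames(co) <- list(rownames(lesions), rownames(lesions))
    consensus[[as.character(K)]] <- co
    coph[i] <- cophenetic_coefficient(co)
  }
  best <- ks[which.max(coph)]   # which.max takes the first (smallest K) tie
  hc <- stats::hclust(stats::as.dist(1 - consensus[[as.character(best)]]),
                      method = "average")
  labels <- stats::cutree(hc, k = best)
  names(labels) <- rownames(lesions)
  zero <- rownames(lesions)[rowSums(as.matrix(lesions)) == 0]
  list(consensus = consensus, cophenetic = coph, selected_k = best,
       labels = labels, zero_samples = zero)
}

#' Fisher-exact discovery of cluster markers
#'
#' For every (marker, cluster) pair, tests whether the marker is lesioned
#' (score > 0, so a synonymous-only gene counts as lesioned) more often
#' inside the cluster than outside, by Fisher's exact test on the 2 x 2 table
#' (lesioned / not) x (in cluster / rest). Markers with `p <= p_max` and
#' in-cluster odds ratio > 1 are assigned to that cluster. The full table,
#' including non-significant rows, is returned.
#'
#' @param lesions a `lesion_matrix` (samples x markers).
#' @param labels integer cluster labels, one per sample (>= 2 clusters, none
#'   empty).
#' @param p_max assignment threshold (default 0.05).
#' @param alternative `"two.sided"` (default) or `"greater"` (one-sided
#'   enrichment).
#' @return data.frame: `marker`, `cluster`, `a` (lesioned, in cluster), `b`
#'   (lesioned, rest), `c` (not lesioned, in cluster), `d` (not lesioned,
#'   rest), `odds_ratio`, `p`, `assigned`.
#' @export
cluster_markers <- function(lesions, labels, p_max = 0.05,
                            alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  lesions <- as.matrix(lesions)
  if (length(labels) != nrow(lesions)) {
    stop("labels must have one entry per sample")
  }
  cl <- sort(unique(labels))
  if (length(cl) < 2L) stop("need at least two clusters")
  if (any(table(factor(labels, levels = cl)) == 0L)) {
    stop("empty cluster in labels")
  }
  lesioned <- lesions > 0
  rows <- list()
  for (k in cl) {
    inc <- labels == k
    a <- colSums(lesioned[inc, , drop = FALSE])
    b <- colSums(lesioned[!inc, , drop = FALSE])
    cc <- sum(inc) - a
    dd <- sum(!inc) - b
    p <- vapply(seq_along(a), function(j) {
      stats::fisher.test(matrix(c(a[j], b[j], cc[j], dd[j]), 2L),
                         alternative = alternative)$p.value
    }, numeric(1))
    orat <- (a * dd) / pmax(b * cc, .Machine$double.eps)
    orat[b == 0 & cc == 0 & a > 0] <- Inf
    rows[[as.character(k)]] <- data.frame(
      marker = colnames(lesions), cluster = k,
      a = as.integer(a), b = as.integer(b), c = as.integer(cc),
      d = as.integer(dd), odds_ratio = orat, p = p,
      assigned = p <= p_max & orat > 1, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a new sample against trained clusters
#'
#' Nearest-centroid assignment in lesion-score space under cosine distance;
#' centroids are the per-cluster mean score vectors of the training matrix.
#' An all-zero row has no direction, so it receives the label of the
#' smallest-norm centroid and is flagged low-confidence.
#'
#' @param row numeric vector of lesion scores, named by marker, in the
#'   training marker order.
#' @param training the training `lesion_matrix`.
#' @param labels training cluster labels (one per training sample).
#' @return list with `label`, `distance` (cosine distance to each centroid),
#'   `low_confidence`.
#' @export
classify_new_sample <- function(row, training, labels) {
  training <- as.matrix(training)
  if (!is.null(names(row))) {
    missing <- setdiff(colnames(training), names(row))
    if (length(missing)) {
      stop("sample lacks markers: ", paste(utils::head(missing), collapse = ", "))
    }
    row <- row[colnames(training)]
  } else if (length(row) != ncol(training)) {
    stop("sample length does not match the training marker list")
  }
  cl <- sort(unique(labels))
  centroids <- t(vapply(cl, function(k) {
    colMeans(training[labels == k, , drop = FALSE])
  }, numeric(ncol(training))))
  if (sum(row^2) == 0) {
    norms <- sqrt(rowSums(centroids^2))
    return(list(label = cl[which.min(norms)],
                distance = stats::setNames(rep(NA_real_, length(cl)), cl),
                low_confidence = TRUE))
  }
  dist <- 1 - apply(centroids, 1L, function(cen) {
    if (sum(cen^2) == 0) return(0)
    cosine_similarity(as.numeric(row), cen)
  })
  list(label = cl[which.min(dist)], distance = stats::setNames(dist, cl),
       low_confidence = FALSE)
}

#' Read / write lesion matrices as TSV
#'
#' On-disk layout: one row per sample (first column `sample`), markers as
#' integer-score columns.
#'
#' @param path file path.
#' @param marker_kind optional named kind vector to re-attach on read.
#' @return `read_lesion_matrix` returns a `lesion_matrix`.
#' @export
read_lesion_matrix <- function(path, marker_kind = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  attr(m, "marker_kind") <- marker_kind
  class(m) <- c("lesion_matrix", class(m))
  m
}

#' @rdname read_lesion_matrix
#' @param lesions a `lesion_matrix`.
#' @export
write_lesion_matrix <- function(lesions, path) {
  df <- data.frame(sample = rownames(lesions), unclass(lesions),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
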