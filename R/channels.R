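.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.BASES <- c("A", "C", "G", "T")

#' The canonical 96 substitution channels
#'
#' Single-base substitutions are classified pyrimidine-centered: six
#' substitution types (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the four
#' possible 5' bases and four possible 3' bases. Channels are ordered
#' lexicographically by substitution, then 5' base, then 3' base (the ordering
#' used by the COSMIC SBS96 catalogs), e.g. `A[C>A]A`, `A[C>A]C`, ...
#'
#' @return Character vector of 96 channel labels.
#' @export
#' @examples
#' head(sbs96_channels())
sbs96_channels <- function() {
  out <- character(96)
  i <- 1L
  for (s in .SUBS) for (p5 in .BASES) for (p3 in .BASES) {
    out[i] <- paste0(p5, "[", s, "]", p3)
    i <- i + 1L
  }
  out
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of short sequences
#'
#' Vectorized over a character vector of equal-length DNA strings. Used to
#' fold purine-reference substitutions onto the pyrimidine strand; for long
#' sequences use [Biostrings::reverseComplement()] instead.
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Map substitutions to their 96-channel label
#'
#' Folds purine-reference records to the reverse-complement pyrimidine channel,
#' so `G>A` at reference-strand context `TGT` maps to `A[C>T]A`.
#'
#' @param ref,alt single reference/alternate bases (reference strand).
#' @param context trinucleotide reference-strand context centered on the
#'   mutated base; its middle base must equal `ref`.
#' @return character vector of channel labels (`NA` where the context contains
#'   an ambiguous base).
#' @export
channel_of <- function(ref, alt, context) {
  stopifnot(length(ref) == length(alt), length(ref) == length(context))
  mid <- substr(context, 2L, 2L)
  bad <- mid != ref
  if (any(bad)) {
    stop("context middle base does not match ref for record(s): ",
         paste(utils::head(which(bad), 10L), collapse = ", "))
  }
  out <- rep(NA_character_, length(ref))
  hasN <- grepl("N", context, fixed = TRUE) | ref == "N" | alt == "N"
  pur <- ref %in% c("A", "G") & !hasN
  pyr <- ref %in% c("C", "T") & !hasN
  if (any(pyr)) {
    out[pyr] <- paste0(substr(context[pyr], 1L, 1L), "[", ref[pyr], ">",
                       alt[pyr], "]", substr(context[pyr], 3L, 3L))
  }
  if (any(pur)) {
    rc_ctx <- revcomp(context[pur])
    rc_ref <- unname(.COMPLEMENT[ref[pur]])
    rc_alt <- unname(.COMPLEMENT[alt[pur]])
    out[pur] <- paste0(substr(rc_ctx, 1L, 1L), "[", rc_ref, ">", rc_alt, "]",
                       substr(rc_ctx, 3L, 3L))
  }
  out
}

#' Construct a signature set
#'
#' A signature set is a 96 x K numeric matrix of non-negative channel
#' probabilities, one column per signature, each column summing to 1. Row
#' names are the channels of [sbs96_channels()] in canonical order.
#'
#' @param x numeric matrix (96 x K) of non-negative values; columns are
#'   normalized to sum to 1.
#' @param names optional signature names (defaults to existing column names).
#' @return A `signature_set` matrix.
#' @export
signature_set <- function(x, names = colnames(x)) {
  x <- as.matrix(x)
  if (nrow(x) != 96L) stop("a signature set must have 96 rows (channels)")
  if (any(x < 0)) stop("signature values must be non-negative")
  cs <- colSums(x)
  if (any(cs <= 0)) stop("every signature must have positive total weight")
  x <- sweep(x, 2L, cs, "/")
  rownames(x) <- sbs96_channels()
  if (is.null(names)) names <- paste0("Sig", seq_len(ncol(x)))
  colnames(x) <- names
  class(x) <- c("signature_set", class(x))
  x
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set:", ncol(x), "signature(s) x 96 channels\n")
  cat("  names:", paste(colnames(x), collapse = ", "), "\n")
  top <- apply(x, 2L, function(v) rownames(x)[which.max(v)])
  cat("  top channel:", paste(paste0(colnames(x), "=", top), collapse = ", "), "\n")
  invisible(x)
}

#' Cosine similarity between channel profiles
#'
#' @param a,b numeric vectors of equal length, or matrices with profiles in
#'   columns (then the full pairwise matrix is returned).
#' @return a scalar, or a matrix of pairwise similarities.
#' @export
cosine_similarity <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- as.matrix(a); b <- as.matrix(b)
    num <- crossprod(a, b)
    na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2))
    return(num / outer(na, nb))
  }
  s <- sum(a * b)
  if (s == 0) return(0)
  s / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Match extracted signatures against a reference set
#'
#' Computes the full pairwise cosine-similarity table between two signature
#' sets sharing the canonical channel order, plus the best reference match per
#' extracted signature.
#'
#' @param extracted,reference `signature_set` matrices (96 x K). The channel
#'   orders must be identical; mismatching orders are an error, never
#'   silently re-sorted.
#' @return list with `similarity` (extracted x reference cosine matrix) and
#'   `best_match` (data.frame: extracted, reference, cosine).
#' @export
match_signatures <- function(extracted, reference) {
  if (!identical(rownames(extracted), rownames(reference))) {
    stop("channel orders differ between signature sets; they must be identical")
  }
  sim <- cosine_similarity(unclass(extracted), unclass(reference))
  best <- apply(sim, 1L, which.max)
  list(
    similarity = sim,
    best_match = data.frame(
      extracted = colnames(extracted),
      reference = colnames(reference)[best],
      cosine = sim[cbind(seq_len(nrow(sim)), best)],
      row.names = NULL
    )
  )
}

#' Built-in synthetic signature fixtures
#'
#' Deterministic signature profiles used throughout the synthetic cohort:
#'
#' * `K1.like` — emulates the AID (activation-induced cytidine deaminase)
#'   kataegis signature: C>G and C>T mutations concentrated at the 16 channels
#'   with a 5' A or T (the WRCY motif preference). Support is entirely
#'   C-centered.
#' * `K2.like` — emulates the POLH (polymerase eta) kataegis signature: T>C
#'   and T>G dominated, with emphasis on a 5' A (the WA motif). Support is
#'   entirely T-centered, hence orthogonal to `K1.like`.
#' * `CpG.deamination` — C>T concentrated at NpCpG channels with a minor
#'   uniform C>A component (an ageing-like clock signature).
#' * `flat` — uniform over all 96 channels (unstructured background).
#'
#' The published K1/K2 kataegis profiles are not redistributable as vectors,
#' so these stand-ins are synthetic by construction; they reproduce the motif
#' structure (AID vs POLH) that the detection and decomposition statistics
#' rely on, not the exact published weights.
#'
#' @param which character vector of fixture names (default: all four).
#' @return A [signature_set()] with the requested columns.
#' @export
#' @examples
#' sigs <- builtin_signatures(c("K1.like", "K2.like"))
#' cosine_similarity(sigs[, 1], sigs[, 2])  # 0: disjoint support
builtin_signatures <- function(which = c("K1.like", "K2.like",
                                         "CpG.deamination", "flat")) {
  ch <- sbs96_channels()
  p5 <- substr(ch, 1L, 1L)
  p3 <- substr(ch, 7L, 7L)
  sub <- substr(ch, 3L, 5L)

  k1 <- numeric(96)
  k1[sub %in% c("C>G", "C>T") & p5 %in% c("A", "T")] <- 1 / 16

  k2 <- numeric(96)
  wa <- sub %in% c("T>C", "T>G") & p5 == "A"
  k2[wa] <- 0.7 / sum(wa)
  rest <- startsWith(sub, "T>") & !wa
  k2[rest] <- 0.3 / sum(rest)

  cpg <- numeric(96)
  tcg <- sub == "C>T" & p3 == "G"
  cpg[tcg] <- 0.8 / sum(tcg)
  ca <- sub == "C>A"
  cpg[ca] <- 0.2 / sum(ca)

  flat <- rep(1 / 96, 96)

  all <- cbind(K1.like = k1, K2.like = k2, CpG.deamination = cpg, flat = flat)
  which <- match.arg(which, colnames(all), several.ok = TRUE)
  signature_set(all[, which, drop = FALSE])
}

#' Read / write signature sets as TSV
#'
#' The on-disk format has channels as rows (first column `channel`, in
#' canonical order) and one column per signature.
#'
#' @param path file path.
#' @return `read_signatures` returns a [signature_set()].
#' @export
read_signatures <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(df[[1L]], sbs96_channels())) {
    stop("signature file ", path, " is not in canonical 96-channel order")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  signature_set(m)
}

#' @rdname read_signatures
#' @param sigs a [signature_set()].
#' @export
write_signatures <- function(sigs, path) {
  df <- data.frame(channel = rownames(sigs), unclass(sigs),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
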