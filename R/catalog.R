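#' Build a 96-channel mutation catalog
#'
#' Counts each sample's single-base substitutions into the 96
#' pyrimidine-centered trinucleotide channels. Records whose reference base is
#' a purine are folded to the reverse-complement channel, so the catalog is
#' strand-agnostic. Row sums equal each sample's usable SNV count.
#'
#' Contexts come from a `context` column on the mutation set when present,
#' otherwise from `context_source`, an indexed genome (`DNAStringSet`). A
#' context whose middle base disagrees with the record's `ref` is an error;
#' records containing an ambiguous base (N) are skipped with a message.
#'
#' @param muts a `mutation_set` data.frame (see [as_mutation_set()]).
#' @param context_source optional `DNAStringSet` used to look up trinucleotide
#'   contexts for records lacking them.
#' @param samples optional character vector fixing the catalog's row set and
#'   order (samples without mutations get zero rows).
#' @return integer matrix, samples x 96, class `mutation_catalog`.
#' @export
#' @examples
#' m <- as_mutation_set(data.frame(sample = "S1", chrom = "chr1", pos = 10L,
#'                                 ref = "C", alt = "T", context = "ACA"))
#' cat96 <- build_catalog(m)
#' cat96[, "A[C>T]A"]
build_catalog <- function(muts, context_source = NULL, samples = NULL) {
  ctx <- if ("context" %in% names(muts)) muts$context else
    rep(NA_character_, nrow(muts))
  missing_ctx <- is.na(ctx)
  if (any(missing_ctx)) {
    if (is.null(context_source)) {
      stop("records lack trinucleotide contexts and no context_source given")
    }
    ctx[missing_ctx] <- lookup_context(muts$chrom[missing_ctx],
                                       muts$pos[missing_ctx], context_source)
  }
  usable <- !(grepl("N", ctx, fixed = TRUE) | muts$ref == "N" |
                muts$alt == "N")
  n_skipped <- sum(!usable)
  if (n_skipped > 0L) {
    message("build_catalog: skipped ", n_skipped,
            " record(s) with ambiguous bases")
  }
  channels <- channel_of(muts$ref[usable], muts$alt[usable], ctx[usable])
  if (is.null(samples)) samples <- unique(muts$sample)
  m <- matrix(0L, length(samples), 96L,
              dimnames = list(samples, sbs96_channels()))
  if (any(usable)) {
    tab <- table(factor(muts$sample[usable], levels = samples),
                 factor(channels, levels = sbs96_channels()))
    m[] <- as.integer(tab)
  }
  attr(m, "n_skipped") <- n_skipped
  class(m) <- c("mutation_catalog", class(m))
  m
}

#' Look up reference-strand trinucleotide contexts
#'
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @param genome a `DNAStringSet` named by chromosome.
#' @return character vector of trinucleotides centered on `pos`.
#' @export
lookup_context <- function(chrom, pos, genome) {
  out <- character(length(chrom))
  for (cn in unique(chrom)) {
    if (!cn %in% names(genome)) stop("chromosome ", cn, " not in genome")
    take <- chrom == cn
    p <- pos[take]
    L <- length(genome[[cn]])
    if (any(p < 2L | p > L - 1L)) {
      stop("position outside context-addressable range on ", cn)
    }
    v <- Biostrings::Views(genome[[cn]], start = p - 1L, width = 3L)
    out[take] <- as.character(v)
  }
  out
}

#' Extract de-novo mutational signatures by NMF
#'
#' For each candidate rank k, runs `n_restarts` seeded NMF factorizations of
#' the transposed catalog (channels x samples) minimizing generalized
#' Kullback-Leibler divergence. Restart components are matched to the
#' best-error restart by cosine similarity; per-k stability is the mean
#' silhouette width of the matched component clusters under cosine distance.
#' The selected k is the largest one whose mean stability reaches
#' `stability_min` (override with `k`). The returned profiles are column-
#' normalized into a [signature_set()] and the activities rescaled so
#' exposures are in mutation counts.
#'
#' @param catalog a `mutation_catalog` (samples x 96).
#' @param k_range candidate ranks, within `[1, min(n_samples, 96)]`.
#' @param n_restarts random restarts per k (>= 10).
#' @param seed integer master seed; per-restart seeds derive from it.
#' @param objective NMF objective, `"kl"` (default) or `"frobenius"`.
#' @param k optional fixed rank overriding model selection.
#' @param stability_min silhouette threshold for the selection rule.
#' @param max_iter,tol passed to [nmf_factorize()].
#' @return list with `signatures` ([signature_set()]), `exposures` (samples x
#'   k counts), `selected_k`, and `stability` (data.frame: k, mean_silhouette,
#'   reconstruction_error).
#' @export
extract_signatures <- function(catalog, k_range = 1:5, n_restarts = 100L,
                               seed = 1L, objective = "kl", k = NULL,
                               stability_min = 0.8, max_iter = 500L,
                               tol = 1e-6) {
  V <- t(unclass(catalog))  # 96 x samples
  zero <- colSums(V) == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " all-zero sample(s) from extraction")
    V <- V[, !zero, drop = FALSE]
  }
  if (ncol(V) < 1L) stop("no non-empty samples in catalog")
  if (n_restarts < 10L) stop("n_restarts must be >= 10")
  if (any(k_range < 1L) || any(k_range > min(ncol(V), 96L))) {
    stop("k_range must lie within [1, min(samples, 96)]")
  }
  ks <- sort(unique(as.integer(k_range)))
  fits <- list(); stab <- numeric(length(ks)); errs <- numeric(length(ks))
  for (i in seq_along(ks)) {
    kk <- ks[i]
    runs <- lapply(seq_len(n_restarts), function(r) {
      nmf_factorize(V, kk, objective = objective, max_iter = max_iter,
                    tol = tol, seed = .spawn_seed(seed, kk * 1000L + r))
    })
    best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "error"))]]
    stab[i] <- .restart_stability(runs, best, kk)
    errs[i] <- best$error
    fits[[i]] <- best
  }
  if (is.null(k)) {
    ok <- which(stab >= stability_min)
    sel <- if (length(ok)) max(ok) else which.max(stab)
  } else {
    sel <- match(as.integer(k), ks)
    if (is.na(sel)) stop("k = ", k, " not in k_range")
  }
  fit <- fits[[sel]]
  cs <- colSums(fit$W)
  W <- sweep(fit$W, 2L, cs, "/")
  H <- fit$H * cs
  sigs <- signature_set(W, names = paste0("Sig", seq_len(ks[sel])))
  expo <- t(H)
  rownames(expo) <- colnames(V)
  colnames(expo) <- colnames(sigs)
  list(signatures = sigs, exposures = expo, selected_k = ks[sel],
       stability = data.frame(k = ks, mean_silhouette = stab,
                              reconstruction_error = errs))
}

# Deterministic per-task seed derived from a master seed; kept below 2^31.
.spawn_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 9349) %% 2147483629)
}

# Mean silhouette of restart components grouped by their best-restart match,
# under cosine distance. For k = 1 the silhouette is undefined; the mean
# pairwise cosine to the reference component is returned instead.
.restart_stability <- function(runs, best, k) {
  comps <- do.call(cbind, lapply(runs, function(r) {
    sweep(r$W, 2L, pmax(colSums(r$W), .Machine$double.eps), "/")
  }))
  ref <- sweep(best$W, 2L, pmax(colSums(best$W), .Machine$double.eps), "/")
  sim_to_ref <- cosine_similarity(comps, ref)  # (runs*k) x k
  if (k == 1L) return(mean(sim_to_ref))
  labels <- apply(sim_to_ref, 1L, which.max)
  if (length(unique(labels)) < 2L) return(0)
  d <- 1 - cosine_similarity(comps, comps)
  d[d < 0] <- 0
  sil <- cluster::silhouette(labels, dmatrix = d)
  mean(sil[, "sil_width"])
}

#' Refit a catalog against fixed signatures (NNLS)
#'
#' Per-sample non-negative least squares of the 96-channel counts against
#' fixed signature profiles. Exposures are in mutation counts (the profiles
#' sum to 1); the per-sample residual L2 norm is attached.
#'
#' @param catalog a `mutation_catalog` (samples x 96) or a single row.
#' @param fixed a [signature_set()] of profiles to refit against.
#' @return matrix samples x signatures of non-negative exposures, with
#'   attribute `residual` (named numeric vector).
#' @export
#' @examples
#' sigs <- builtin_signatures(c("K1.like", "K2.like"))
#' sim <- simulate_catalog(1, 100, sigs, c(1, 0), seed = 7)
#' round(refit_exposures(sim$catalog, sigs))
refit_exposures <- function(catalog, fixed) {
  if (is.null(dim(catalog))) catalog <- matrix(catalog, 1L, 96L)
  if (ncol(catalog) != 96L) stop("catalog must have 96 channels")
  A <- unclass(fixed)
  n <- nrow(catalog)
  expo <- matrix(0, n, ncol(A),
                 dimnames = list(rownames(catalog), colnames(A)))
  resid <- stats::setNames(numeric(n), rownames(catalog))
  for (i in seq_len(n)) {
    sol <- nnls_solve(A, as.numeric(catalog[i, ]))
    expo[i, ] <- sol$x
    resid[i] <- sol$residual
  }
  attr(expo, "residual") <- resid
  expo
}

#' Read / write mutation catalogs as TSV
#'
#' On-disk layout: channels as rows (column `channel`, canonical order), one
#' column per sample.
#'
#' @param path file path.
#' @return `read_catalog` returns a `mutation_catalog` matrix.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(df[[1L]], sbs96_channels())) {
    stop("catalog file ", path, " is not in canonical 96-channel order")
  }
  m <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(m) <- sbs96_channels()
  class(m) <- c("mutation_catalog", class(m))
  m
}

#' @rdname read_catalog
#' @param catalog a `mutation_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(channel = sbs96_channels(),
                   t(unclass(catalog)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
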