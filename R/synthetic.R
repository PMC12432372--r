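#' Simulate a reference genome for the synthetic cohort
#'
#' Generates random chromosome sequences (i.i.d. A/C/G/T) and returns them as
#' a [Biostrings::DNAStringSet]. Random sequence gives every trinucleotide
#' context a frequency near 1/32 per strand, so mutations of any signature can
#' be placed anywhere along a chromosome.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param seed integer seed.
#' @return `DNAStringSet` named by chromosome.
#' @export
simulate_genome <- function(chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                            seed = 1L) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == "")) {
    stop("chrom_lengths must be a named vector")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  seqs <- vapply(chrom_lengths, function(L) {
    paste(sample(.BASES, L, replace = TRUE), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

# Index a genome by pyrimidine-centered trinucleotide context.
# Returns, per chromosome: positions (2..L-1), the pyrimidine-folded context
# at each, and whether the reference base is itself a pyrimidine.
.context_index <- function(genome) {
  lapply(stats::setNames(seq_along(genome), names(genome)), function(i) {
    chars <- strsplit(as.character(genome[[i]]), "", fixed = TRUE)[[1]]
    L <- length(chars)
    pos <- 2:(L - 1L)
    tri <- paste0(chars[pos - 1L], chars[pos], chars[pos + 1L])
    mid <- chars[pos]
    is_pyr <- mid %in% c("C", "T")
    ctx <- tri
    if (any(!is_pyr)) ctx[!is_pyr] <- revcomp(tri[!is_pyr])
    list(pos = pos, ref = mid, context = tri, pyr_context = ctx,
         is_pyr = is_pyr)
  })
}

#' Specify a synthetic mutation cohort
#'
#' @param n_samples number of tumor genomes to simulate.
#' @param background_rate mean number of background somatic SNVs per genome
#'   (Poisson-distributed per sample).
#' @param signature_mix non-negative weights over the supplied signatures:
#'   either a vector (shared by all samples) or an `n_samples x K` matrix.
#' @param kataegis_plan `NULL`, or a data.frame with columns `sample`
#'   (integer index), `chrom`, `locus` (start bp), `n_mutations`,
#'   `max_span_bp`, `source_signature` (name in the signature set); each row
#'   plants one clustered-mutation run. A run intended to be detectable needs
#'   `n_mutations >= 10` and `max_span_bp <= 10000`.
#' @param seed integer master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples, background_rate, signature_mix,
                        kataegis_plan = NULL, seed = 1L) {
  stopifnot(n_samples >= 1, background_rate >= 0)
  if (is.matrix(signature_mix)) {
    stopifnot(nrow(signature_mix) == n_samples)
  }
  if (any(signature_mix < 0)) stop("signature_mix weights must be non-negative")
  if (!is.null(kataegis_plan)) {
    need <- c("sample", "chrom", "locus", "n_mutations", "max_span_bp",
              "source_signature")
    if (!all(need %in% names(kataegis_plan))) {
      stop("kataegis_plan must have columns: ", paste(need, collapse = ", "))
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 background_rate = background_rate,
                 signature_mix = signature_mix,
                 kataegis_plan = kataegis_plan,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate per-sample somatic SNVs
#'
#' Background mutations are placed uniformly along each chromosome
#' (proportionally to its length) and sorted, so intermutation distances are
#' approximately exponential — the null the kataegis detector assumes. Each
#' mutation's substitution channel is drawn from a generating signature chosen
#' by the per-sample mixture weights, and its position is drawn uniformly
#' among genome positions carrying the channel's trinucleotide context.
#' Planted kataegis runs are inserted as `n_mutations` positions inside
#' `[locus, locus + max_span_bp]` drawn from the stated source signature.
#'
#' Substitutions are stored on the reference strand (VCF semantics): a C>T
#' channel mutation landing on a genomic G appears as `G>A` with its
#' reference-strand context; pyrimidine folding happens only in
#' [build_catalog()]. Every record carries its generating-signature label
#' (`signature`) and a `planted` flag for recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @param signatures a [signature_set()] with the signatures named by
#'   `spec$signature_mix` / `kataegis_plan$source_signature`.
#' @param genome a `DNAStringSet` (see [simulate_genome()]).
#' @return A data.frame (class `mutation_set`) with columns `sample`, `chrom`,
#'   `pos`, `ref`, `alt`, `context`, `signature`, `planted`, sorted by
#'   (sample, chrom, pos).
#' @export
simulate_mutations <- function(spec, signatures, genome) {
  stopifnot(inherits(spec, "cohort_spec"))
  K <- ncol(signatures)
  mix <- spec$signature_mix
  if (!is.matrix(mix)) mix <- matrix(mix, spec$n_samples, K, byrow = TRUE)
  if (ncol(mix) != K) stop("signature_mix width must match signature count")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  idx <- .context_index(genome)
  lens <- vapply(genome, length, integer(1))
  ch <- sbs96_channels()
  ch_context <- paste0(substr(ch, 1L, 1L), substr(ch, 3L, 3L),
                       substr(ch, 7L, 7L))  # pyrimidine-centered trinucleotide
  ch_alt <- substr(ch, 5L, 5L)
  samples <- sprintf("S%03d", seq_len(spec$n_samples))

  # positions by (chrom, context) for fast uniform draws
  by_ctx <- lapply(idx, function(ci) split(seq_along(ci$pos), ci$pyr_context))

  draw_records <- function(chrom, n, sig_ids, window = NULL) {
    # sig_ids: generating signature index per mutation
    ci <- idx[[chrom]]
    channels <- vapply(sig_ids, function(s) {
      sample.int(96L, 1L, prob = signatures[, s])
    }, integer(1))
    avail <- by_ctx[[chrom]]
    if (!is.null(window)) {
      keep <- ci$pos >= window[1] & ci$pos <= window[2]
      avail <- lapply(avail, function(ii) ii[keep[ii]])
    }
    sel <- integer(length(channels))
    for (ctx in unique(ch_context[channels])) {
      rows <- which(ch_context[channels] == ctx)
      pool <- avail[[ctx]]
      if (length(pool) < length(rows)) {
        stop("not enough positions with context ", ctx, " on ", chrom,
             if (!is.null(window)) paste0(" in window [", window[1], ", ",
                                          window[2], "]"))
      }
      sel[rows] <- pool[sample.int(length(pool), length(rows))]
    }
    alt_pyr <- ch_alt[channels]
    alt <- ifelse(idx[[chrom]]$is_pyr[sel], alt_pyr,
                  unname(.COMPLEMENT[alt_pyr]))
    data.frame(chrom = chrom, pos = ci$pos[sel], ref = ci$ref[sel],
               alt = alt, context = ci$context[sel],
               signature = colnames(signatures)[sig_ids],
               stringsAsFactors = FALSE)
  }

  out <- vector("list", spec$n_samples)
  for (s in seq_len(spec$n_samples)) {
    n_bg <- stats::rpois(1L, spec$background_rate)
    w <- mix[s, ]
    recs <- list()
    if (n_bg > 0L) {
      if (sum(w) <= 0) stop("sample ", s, " has all-zero signature_mix")
      sig_ids <- sample.int(K, n_bg, replace = TRUE, prob = w)
      chroms <- sample(names(genome), n_bg, replace = TRUE,
                       prob = lens / sum(lens))
      recs <- lapply(names(genome), function(cn) {
        take <- chroms == cn
        if (!any(take)) return(NULL)
        draw_records(cn, sum(take), sig_ids[take])
      })
    }
    plan <- spec$kataegis_plan
    if (!is.null(plan)) {
      plan_s <- plan[plan$sample == s, , drop = FALSE]
      for (r in seq_len(nrow(plan_s))) {
        p <- plan_s[r, ]
        if (!p$chrom %in% names(genome)) {
          stop("kataegis locus on unknown chromosome ", p$chrom)
        }
        if (p$locus < 2 || p$locus + p$max_span_bp > lens[[p$chrom]] - 1) {
          stop("kataegis locus ", p$chrom, ":", p$locus,
               " outside genome bounds")
        }
        sig_id <- match(p$source_signature, colnames(signatures))
        if (is.na(sig_id)) stop("unknown source signature ", p$source_signature)
        kat <- draw_records(p$chrom, p$n_mutations,
                            rep(sig_id, p$n_mutations),
                            window = c(p$locus, p$locus + p$max_span_bp))
        kat$planted <- TRUE
        recs <- c(recs, list(kat))
      }
    }
    recs <- Filter(Negate(is.null), recs)
    if (length(recs) == 0L) {
      out[[s]] <- NULL
      next
    }
    recs <- lapply(recs, function(d) {
      if (is.null(d$planted)) d$planted <- FALSE
      d
    })
    df <- do.call(rbind, recs)
    df <- df[!duplicated(df[, c("chrom", "pos")]), , drop = FALSE]
    df$sample <- samples[s]
    out[[s]] <- df
  }
  res <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(res)) {
    res <- data.frame(sample = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      context = character(), signature = character(),
                      planted = logical())
  }
  as_mutation_set(res[, c("sample", "chrom", "pos", "ref", "alt", "context",
                          "signature", "planted")])
}

#' Coerce a data.frame of SNV records to a mutation set
#'
#' Validates single-nucleotide records (`ref != alt`, single bases) and sorts
#' them by (sample, chromosome, position), the invariant every downstream
#' operation assumes.
#'
#' @param df data.frame with at least `sample`, `chrom`, `pos`, `ref`, `alt`;
#'   optionally `context` (reference-strand trinucleotide).
#' @return the sorted, validated data.frame with class `mutation_set`.
#' @export
as_mutation_set <- function(df) {
  need <- c("sample", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("mutation set needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df)) {
    if (any(nchar(df$ref) != 1L | nchar(df$alt) != 1L)) {
      stop("only single-nucleotide substitutions are supported")
    }
    if (any(df$ref == df$alt)) stop("ref must differ from alt")
  }
  df <- df[order(df$sample, df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- unique(c("mutation_set", class(df)))
  df
}

#' Simulate a mutation catalog directly from signature mixtures
#'
#' Draws each sample's 96-channel counts from a multinomial over the mixture
#' profile, bypassing genomic placement. Useful for signature-recovery
#' experiments where positions are irrelevant.
#'
#' @param n_samples number of samples.
#' @param n_mutations mutations per sample (scalar or length `n_samples`).
#' @param signatures a [signature_set()].
#' @param mix mixture weights: vector of length K, or `n_samples x K` matrix.
#' @param seed integer seed.
#' @return list with `catalog` (samples x 96 counts) and `exposures`
#'   (samples x K expected counts, the ground truth).
#' @export
simulate_catalog <- function(n_samples, n_mutations, signatures, mix,
                             seed = 1L) {
  K <- ncol(signatures)
  if (!is.matrix(mix)) mix <- matrix(mix, n_samples, K, byrow = TRUE)
  mix <- mix / rowSums(mix)
  n_mutations <- rep_len(n_mutations, n_samples)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cat_m <- matrix(0L, n_samples, 96L,
                  dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                                  sbs96_channels()))
  for (s in seq_len(n_samples)) {
    profile <- drop(unclass(signatures) %*% mix[s, ])
    cat_m[s, ] <- as.integer(stats::rmultinom(1L, n_mutations[s], profile))
  }
  list(catalog = cat_m, exposures = mix * n_mutations)
}

#' Specify a synthetic lesion cohort with planted cluster structure
#'
#' Emulates a marker-by-sample lesion matrix with cluster-specific marker
#' enrichment: each cluster owns `markers_per_cluster` markers, lesioned with
#' probability `enrichment_own` in its members and `enrichment_other`
#' elsewhere. Marker kinds cycle through the four scored lesion classes
#' (gene mutation, CNV gain peak, CNV loss peak, SV).
#'
#' @param n_clusters number of planted clusters (>= 2).
#' @param markers_per_cluster markers owned by each cluster (>= 1).
#' @param samples_per_cluster samples per cluster.
#' @param enrichment_own,enrichment_other lesion probability of a cluster's
#'   own marker in its members vs in other samples.
#' @param n_null_markers extra markers with no cluster association (lesioned
#'   everywhere at `enrichment_other`).
#' @param seed integer seed.
#' @return A `cluster_spec` list. Defaults give 3 x 42 + 1 = 127 markers over
#'   120 samples, the shape of the FL marker matrix.
#' @export
cluster_spec <- function(n_clusters = 3L, markers_per_cluster = 42L,
                         samples_per_cluster = 40L,
                         enrichment_own = 0.9, enrichment_other = 0.05,
                         n_null_markers = 1L, seed = 1L) {
  if (n_clusters < 2L) stop("n_clusters must be >= 2")
  if (markers_per_cluster < 1L) stop("markers_per_cluster must be >= 1")
  if (enrichment_own < 0 || enrichment_own > 1 ||
      enrichment_other < 0 || enrichment_other > 1) {
    stop("enrichment probabilities must lie in [0, 1]")
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 markers_per_cluster = as.integer(markers_per_cluster),
                 samples_per_cluster = as.integer(samples_per_cluster),
                 enrichment_own = enrichment_own,
                 enrichment_other = enrichment_other,
                 n_null_markers = as.integer(n_null_markers),
                 seed = as.integer(seed)),
            class = "cluster_spec")
}

.LESION_KINDS <- c("mutation", "cnv_gain_peak", "cnv_loss_peak", "sv")

#' Simulate per-sample lesion calls with known cluster labels
#'
#' For every (sample, marker) pair that is lesioned, a raw call is emitted in
#' the class of the marker: gene mutations carry a consequence (mostly
#' nonsilent/indel, occasionally synonymous), CNV markers carry an absolute
#' copy number drawn across the scoring tiers so every encoding branch is
#' exercised (including occasional neutral copy numbers that must score 0),
#' and SV markers carry a presence flag.
#'
#' @param spec a [cluster_spec()].
#' @return list with `calls` (data.frame: sample, marker, kind, detail),
#'   `markers` (data.frame: marker, kind, cluster — cluster `NA` for null
#'   markers), and `truth` (data.frame: sample, cluster).
#' @export
simulate_lesions <- function(spec) {
  stopifnot(inherits(spec, "cluster_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n_samp <- spec$n_clusters * spec$samples_per_cluster
  samples <- sprintf("S%03d", seq_len(n_samp))
  truth <- data.frame(sample = samples,
                      cluster = rep(seq_len(spec$n_clusters),
                                    each = spec$samples_per_cluster))
  n_mark <- spec$n_clusters * spec$markers_per_cluster + spec$n_null_markers
  markers <- data.frame(
    marker = sprintf("M%03d", seq_len(n_mark)),
    kind = rep_len(.LESION_KINDS, n_mark),
    cluster = c(rep(seq_len(spec$n_clusters),
                    each = spec$markers_per_cluster),
                rep(NA_integer_, spec$n_null_markers))
  )
  calls <- list()
  for (mi in seq_len(n_mark)) {
    own <- !is.na(markers$cluster[mi]) & truth$cluster == markers$cluster[mi]
    p <- ifelse(own, spec$enrichment_own, spec$enrichment_other)
    hit <- stats::runif(n_samp) < p
    if (!any(hit)) next
    kind <- markers$kind[mi]
    n_hit <- sum(hit)
    detail <- switch(
      kind,
      mutation = sample(c("nonsilent", "indel", "synonymous"), n_hit,
                        replace = TRUE, prob = c(0.7, 0.15, 0.15)),
      cnv_gain_peak = as.character(round(ifelse(
        stats::runif(n_hit) < 0.5,
        stats::runif(n_hit, 2.4, 3.7),     # low-grade gain tier
        stats::runif(n_hit, 3.71, 6.0)), 3)),  # high-grade gain tier
      cnv_loss_peak = as.character(round(ifelse(
        stats::runif(n_hit) < 0.5,
        stats::runif(n_hit, 0.81, 1.6),    # low-grade loss tier
        stats::runif(n_hit, 0.1, 0.8)), 3)),   # high-grade loss tier
      sv = rep("1", n_hit)
    )
    calls[[length(calls) + 1L]] <- data.frame(
      sample = samples[hit], marker = markers$marker[mi],
      kind = if (kind == "mutation") "mutation" else
        if (kind == "sv") "sv" else "cnv",
      detail = detail, stringsAsFactors = FALSE)
    # occasional neutral copy-number record at CNV markers: scores 0
    if (kind %in% c("cnv_gain_peak", "cnv_loss_peak")) {
      neutral <- which(!hit & stats::runif(n_samp) < 0.02)
      if (length(neutral)) {
        calls[[length(calls) + 1L]] <- data.frame(
          sample = samples[neutral], marker = markers$marker[mi],
          kind = "cnv",
          detail = as.character(round(stats::runif(length(neutral), 1.7, 2.3),
                                      3)),
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample = character(), marker = character(),
               kind = character(), detail = character())
  calls <- calls[order(calls$sample, calls$marker), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, markers = markers, truth = truth)
}

#' Write a synthetic cohort to disk
#'
#' Emits one VCF v4.2 file per sample (`<sample>.vcf`, 1-based positions,
#' trinucleotide context and generating signature in INFO), a lesion-calls
#' TSV, and a truth TSV with the planted cluster labels. The files round-trip
#' losslessly through [read_mutations_vcf()] / [read_lesions()].
#'
#' @param mutations a `mutation_set` data.frame.
#' @param lesions result of [simulate_lesions()], or `NULL` to skip.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(mutations, lesions = NULL, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", outdir)
  }
  files <- character()
  for (s in unique(mutations$sample)) {
    path <- file.path(outdir, paste0(s, ".vcf"))
    write_vcf(mutations[mutations$sample == s, , drop = FALSE], path,
              sample = s)
    files <- c(files, path)
  }
  if (!is.null(lesions)) {
    lpath <- file.path(outdir, "lesions.tsv")
    utils::write.table(lesions$calls, lpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tpath <- file.path(outdir, "truth.tsv")
    utils::write.table(lesions$truth, tpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mpath <- file.path(outdir, "markers.tsv")
    utils::write.table(lesions$markers, mpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, lpath, tpath, mpath)
  }
  invisible(files)
}

# Minimal VCF v4.2 writer: plain-text, one sample per file, context and
# generating-signature labels carried in INFO so the cohort round-trips.
write_vcf <- function(muts, path, sample = muts$sample[1]) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##source=flsubtype-", as.character(utils::packageVersion("flsubtype"))),
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Reference-strand trinucleotide context\">",
    "##INFO=<ID=SIG,Number=1,Type=String,Description=\"Generating signature label\">",
    "##INFO=<ID=KAT,Number=0,Type=Flag,Description=\"Planted kataegis member\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(muts)) {
    info <- paste0(
      ifelse(is.na(muts$context) | is.null(muts$context), "",
             paste0("CTX=", muts$context)),
      if (!is.null(muts$signature)) paste0(";SIG=", muts$signature) else "",
      if (!is.null(muts$planted)) ifelse(muts$planted, ";KAT", "") else "")
    info <- sub("^;", "", info)
    info[info == ""] <- "."
    writeLines(paste(muts$chrom, muts$pos, ".", muts$ref, muts$alt, ".",
                     "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}

#' Read somatic SNVs from VCF
#'
#' Reads a single-sample VCF v4.2 via \pkg{vcfR}, keeping only biallelic
#' single-nucleotide records. CTX/SIG/KAT INFO fields written by
#' [write_cohort()] are restored when present.
#'
#' @param path VCF file path.
#' @param sample sample id to assign (default: file name without extension).
#' @return a `mutation_set` data.frame.
#' @export
read_mutations_vcf <- function(path, sample = NULL) {
  if (is.null(sample)) sample <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(as_mutation_set(data.frame(
      sample = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), context = character())))
  }
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT)
  fix <- fix[keep, , drop = FALSE]
  getinfo <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(?:^|;)", key, "=([^;]*)"),
                                      fix$INFO, perl = TRUE))
    out <- rep(NA_character_, nrow(fix))
    has <- grepl(paste0("(^|;)", key, "="), fix$INFO)
    out[has] <- sub(paste0(".*(?:^|;)", key, "="), "", m)
    out
  }
  df <- data.frame(sample = sample, chrom = fix$CHROM,
                   pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                   context = getinfo("CTX"), stringsAsFactors = FALSE)
  sig <- getinfo("SIG")
  if (any(!is.na(sig))) df$signature <- sig
  df$planted <- grepl("(^|;)KAT($|;)", fix$INFO)
  as_mutation_set(df)
}

#' Read somatic SNVs from a TSV table
#'
#' Expects columns `sample`, `chrom`, `pos`, `ref`, `alt` and optionally
#' `context`.
#'
#' @param path TSV file path.
#' @return a `mutation_set` data.frame.
#' @export
read_mutations_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_mutation_set(df)
}

#' Read lesion calls from TSV
#'
#' @param path TSV with columns `sample`, `marker`, `kind`
#'   (mutation/cnv/sv), `detail`.
#' @return data.frame of lesion calls.
#' @export
read_lesions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample", "marker", "kind", "detail")
  if (!all(need %in% names(df))) {
    stop("lesion TSV needs columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$kind), c("mutation", "cnv", "sv"))
  if (length(bad)) stop("unknown lesion kind(s): ", paste(bad, collapse = ", "))
  df
}
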