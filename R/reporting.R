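#' Two-group and categorical comparisons
#'
#' The reporting convention of the cohort analyses: continuous variables are
#' compared by the two-sided Mann-Whitney (Wilcoxon rank-sum) test — exact
#' when both groups have at most `exact_max` observations and no ties,
#' otherwise the tie-corrected normal approximation with continuity
#' correction — and categorical variables by the chi-square or Fisher's
#' exact test.
#'
#' @param values numeric vector (rank-sum) or factor-like vector
#'   (chisq/fisher); for the categorical tests a pre-tabulated contingency
#'   matrix may be passed directly (then `groups` is ignored).
#' @param groups grouping vector, same length as `values`; two groups for
#'   rank-sum, any number for the categorical tests.
#' @param test `"ranksum"`, `"chisq"` or `"fisher"`.
#' @param exact_max exact-path cutoff for the rank-sum test (default 10 per
#'   group).
#' @return data.frame: `variable_type`, `test`, `statistic`, `p`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3, 10, 20, 30), rep(c("a", "b"), each = 3))
compare_groups <- function(values, groups,
                           test = c("ranksum", "chisq", "fisher"),
                           exact_max = 10L) {
  test <- match.arg(test)
  if (is.matrix(values)) {
    if (test == "ranksum") stop("rank-sum requires raw values, not a table")
    tab <- values
  } else {
    groups <- as.factor(groups)
    if (any(table(groups) == 0L) || nlevels(groups) < 2L) {
      stop("need at least two non-empty groups")
    }
    if (test != "ranksum") tab <- table(values, groups)
  }
  if (test == "ranksum") {
    if (nlevels(groups) != 2L) stop("rank-sum compares exactly two groups")
    x <- values[groups == levels(groups)[1L]]
    y <- values[groups == levels(groups)[2L]]
    ties <- anyDuplicated(c(x, y)) > 0L
    use_exact <- max(length(x), length(y)) <= exact_max && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                         correct = !use_exact))
    out <- data.frame(variable_type = "continuous", test = "rank-sum",
                      statistic = unname(wt$statistic), p = wt$p.value)
  } else if (test == "chisq") {
    ct <- suppressWarnings(stats::chisq.test(tab))
    out <- data.frame(variable_type = "categorical", test = "chi-square",
                      statistic = unname(ct$statistic), p = ct$p.value)
  } else {
    ft <- stats::fisher.test(tab)
    out <- data.frame(variable_type = "categorical", test = "Fisher",
                      statistic = NA_real_, p = ft$p.value)
  }
  out
}

#' Assemble a pipeline configuration
#'
#' All knobs of the end-to-end run in one validated list; can also be read
#' from YAML or JSON via [read_run_config()]. A seed is mandatory — every
#' random draw in the pipeline derives from it, making reruns bit-identical.
#'
#' @param outdir output directory.
#' @param seed integer master seed (required).
#' @param n_samples,background_rate,signature_mix,kataegis_per_sample
#'   synthetic-cohort settings: cohort size, mean SNVs per genome, mixture
#'   weights over the built-in signature fixtures, and how many 12-mutation
#'   kataegis runs to plant per sample (alternating K1-like / K2-like
#'   sources).
#' @param chrom_lengths named chromosome lengths for the synthetic genome.
#' @param window_n,max_span_bp,p_threshold kataegis detector settings.
#' @param k_range,n_runs consensus-clustering settings.
#' @param lesion_spec a [cluster_spec()] (its seed is overridden from the
#'   master seed).
#' @return a validated `run_config` list.
#' @export
run_config <- function(outdir, seed, n_samples = 40L,
                       background_rate = 2000,
                       signature_mix = c(K1.like = 0.2, K2.like = 0.2,
                                         CpG.deamination = 0.3, flat = 0.3),
                       kataegis_per_sample = 2L,
                       chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                       window_n = 10L, max_span_bp = 10000L,
                       p_threshold = 1e-4, k_range = 2:8, n_runs = 100L,
                       lesion_spec = cluster_spec()) {
  if (missing(seed) || is.null(seed)) stop("a master seed is required")
  stopifnot(p_threshold > 0, max_span_bp > 0, window_n >= 2, n_runs >= 30)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 n_samples = as.integer(n_samples),
                 background_rate = background_rate,
                 signature_mix = signature_mix,
                 kataegis_per_sample = as.integer(kataegis_per_sample),
                 chrom_lengths = chrom_lengths, window_n = as.integer(window_n),
                 max_span_bp = as.integer(max_span_bp),
                 p_threshold = p_threshold, k_range = k_range,
                 n_runs = as.integer(n_runs), lesion_spec = lesion_spec),
            class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file whose keys match the
#'   [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$seed)) stop("configuration must provide a seed")
  ls_args <- raw$lesion_spec
  raw$lesion_spec <- if (is.null(ls_args)) cluster_spec() else
    do.call(cluster_spec, ls_args)
  if (!is.null(raw$signature_mix)) raw$signature_mix <- unlist(raw$signature_mix)
  if (!is.null(raw$chrom_lengths)) raw$chrom_lengths <- unlist(raw$chrom_lengths)
  do.call(run_config, raw)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Sequences every stage: genome + cohort simulation, VCF/TSV output,
#' 96-channel catalog, signature extraction and NNLS refitting, kataegis
#' detection with K1/K2 decomposition and region annotation, lesion encoding
#' and NMF consensus clustering with Fisher marker discovery, plus
#' group-comparison reports over the synthetic labels. Writes all results as
#' TSV/JSON under `config$outdir` and finishes with a manifest carrying the
#' package version, seed, and per-file MD5 checksums; reruns with the same
#' configuration are bit-identical.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress lines.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[flsubtype] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  sigs <- builtin_signatures()

  say("simulate: cohort of ", config$n_samples, " genomes")
  sim <- stage("simulate", {
    genome <- simulate_genome(config$chrom_lengths,
                              seed = .spawn_seed(config$seed, 1L))
    plan <- NULL
    if (config$kataegis_per_sample > 0L) {
      plan <- do.call(rbind, lapply(seq_len(config$n_samples), function(s) {
        k <- config$kataegis_per_sample
        data.frame(sample = s, chrom = names(config$chrom_lengths)[1L],
                   locus = 50000 + (seq_len(k) - 1L) * 200000,
                   n_mutations = 12L, max_span_bp = 2000L,
                   source_signature = rep(c("K1.like", "K2.like"),
                                          length.out = k))
      }))
    }
    # per-sample mixture heterogeneity around the configured weights
    # (real cohorts show strong inter-sample exposure variation, and
    # signature extraction is only identifiable when mixtures vary)
    base <- config$signature_mix[colnames(sigs)]
    base <- base / sum(base)
    old <- .Random.seed_save()
    set.seed(.spawn_seed(config$seed, 6L))
    mixm <- t(vapply(seq_len(config$n_samples), function(s) {
      w <- stats::rgamma(length(base), shape = 8 * base + 0.2)
      w / sum(w)
    }, numeric(length(base))))
    .Random.seed_restore(old)
    spec <- cohort_spec(config$n_samples, config$background_rate,
                        mixm, kataegis_plan = plan,
                        seed = .spawn_seed(config$seed, 2L))
    muts <- simulate_mutations(spec, sigs, genome)
    lesions <- simulate_lesions(local({
      ls <- config$lesion_spec
      ls$seed <- .spawn_seed(config$seed, 3L)
      ls
    }))
    write_cohort(muts, lesions, file.path(config$outdir, "cohort"))
    list(genome = genome, muts = muts, lesions = lesions)
  })
  say("simulate: ", nrow(sim$muts), " SNVs, ",
      nrow(sim$lesions$calls), " lesion calls")

  say("catalog: building 96-channel catalog")
  cat96 <- stage("catalog", build_catalog(sim$muts))
  write_catalog(cat96, file.path(config$outdir, "catalog.tsv"))

  say("signatures: extraction and refitting")
  sig_res <- stage("signatures", {
    ext <- extract_signatures(cat96, k_range = 2:5, n_restarts = 10L,
                              seed = .spawn_seed(config$seed, 4L))
    refit <- refit_exposures(cat96, sigs)
    match <- match_signatures(ext$signatures, sigs)
    write_signatures(ext$signatures,
                     file.path(config$outdir, "signatures_denovo.tsv"))
    utils::write.table(
      data.frame(sample = rownames(refit), refit,
                 residual = attr(refit, "residual"), check.names = FALSE),
      file.path(config$outdir, "exposures.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(extraction = ext, refit = refit, match = match)
  })
  say("signatures: selected k = ", sig_res$extraction$selected_k)

  say("kataegis: detection and K1/K2 decomposition")
  kat <- stage("kataegis", {
    ev <- detect_kataegis(sim$muts, threshold = config$p_threshold,
                          window_n = config$window_n,
                          max_span_bp = config$max_span_bp)
    ev <- decompose_events(ev, sim$muts,
                           builtin_signatures(c("K1.like", "K2.like")))
    # synthetic annotation of the synthetic genome: K1-planted loci are
    # declared Ig switch regions, K2-planted loci get a TSS anchor at the
    # center of the planted window
    if (config$kataegis_per_sample > 0L) {
      k <- seq_len(config$kataegis_per_sample)
      loci <- 50000 + (k - 1L) * 200000
      is_k1 <- k %% 2L == 1L
      anno_dir <- file.path(config$outdir, "annotation")
      dir.create(anno_dir, showWarnings = FALSE, recursive = TRUE)
      ig_path <- file.path(anno_dir, "ig_synthetic.bed")
      tss_path <- file.path(anno_dir, "tss_synthetic.bed")
      chrom1 <- names(config$chrom_lengths)[1L]
      writeLines(sprintf("%s\t%d\t%d\tS", chrom1, loci[is_k1] - 1000L,
                         loci[is_k1] + 3000L), ig_path)
      tss_anchor <- loci[!is_k1] + 1000L
      if (length(tss_anchor) == 0L) tss_anchor <- config$chrom_lengths[[1L]] - 1L
      writeLines(sprintf("%s\t%d\t%d\tTSS", chrom1, tss_anchor - 1L,
                         tss_anchor), tss_path)
      ev <- annotate_events(ev, ig_path, tss_path)
    }
    summ <- summarize_samples(ev, samples = unique(sim$muts$sample))
    bed <- data.frame(chrom = ev$chrom, start0 = ev$start - 1L, end = ev$end,
                      sample = ev$sample, n_mutations = ev$n_mut, p = ev$p,
                      k1_contribution = ev$k1_contribution,
                      dominance = ev$dominance)
    if (!is.null(ev$region_class)) bed$region_class <- ev$region_class
    utils::write.table(bed, file.path(config$outdir, "kataegis_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summ, file.path(config$outdir,
                                         "kataegis_summary.json"),
                         dataframe = "rows", pretty = TRUE, digits = NA)
    list(events = ev, summary = summ)
  })
  say("kataegis: ", nrow(kat$events), " events in ",
      sum(kat$summary$n_events > 0), " samples")

  say("subtype: lesion encoding and consensus clustering")
  sub <- stage("subtype", {
    lm <- encode_lesions(sim$lesions$calls, sim$lesions$markers,
                         samples = sim$lesions$truth$sample)
    cons <- nmf_consensus(lm, k_range = config$k_range,
                          n_runs = config$n_runs,
                          seed = .spawn_seed(config$seed, 5L))
    mk <- cluster_markers(lm, cons$labels)
    write_lesion_matrix(lm, file.path(config$outdir, "lesion_matrix.tsv"))
    utils::write.table(mk, file.path(config$outdir, "marker_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(cophenetic = as.list(cons$cophenetic),
           selected_k = cons$selected_k,
           labels = as.list(cons$labels)),
      file.path(config$outdir, "clusters.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
    utils::write.table(
      as.data.frame(cons$consensus[[as.character(cons$selected_k)]]),
      file.path(config$outdir, "consensus_selectedK.tsv"),
      sep = "\t", quote = FALSE, row.names = TRUE)
    list(matrix = lm, consensus = cons, markers = mk)
  })
  say("subtype: selected K = ", sub$consensus$selected_k)

  say("report: group comparisons")
  cmp <- stage("report", {
    ev <- kat$events
    rows <- list()
    # K1 contribution of events by region class (the K1-in-Ig-switch vs
    # K2-in-TSS contrast), rank-sum on the continuous contribution and
    # Fisher on the dominance label
    if (!is.null(ev$region_class) && nrow(ev) > 0) {
      in_ig <- ifelse(startsWith(ev$region_class, "Ig"), "Ig", "non-Ig")
      ok <- !is.na(ev$k1_contribution)
      if (length(unique(in_ig[ok])) == 2L) {
        rows[["k1_by_region"]] <-
          cbind(variable = "k1_contribution_vs_region",
                compare_groups(ev$k1_contribution[ok], in_ig[ok], "ranksum"))
        rows[["dom_by_region"]] <-
          cbind(variable = "dominance_vs_region",
                compare_groups(ev$dominance[ok], in_ig[ok], "fisher"))
      }
    }
    out <- do.call(rbind, rows)
    if (!is.null(out)) {
      utils::write.table(out, file.path(config$outdir,
                                        "group_comparisons.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  })

  manifest <- file.path(config$outdir, "manifest.json")
  files <- sort(setdiff(list.files(config$outdir, recursive = TRUE),
                        "manifest.json"))
  jsonlite::write_json(
    list(package = "flsubtype",
         version = as.character(utils::packageVersion("flsubtype")),
         seed = config$seed,
         checksums = as.list(tools::md5sum(
           file.path(config$outdir, files))[file.path(config$outdir, files)] |>
             stats::setNames(files))),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  say("done: manifest at ", manifest)
  invisible(list(sim = sim, catalog = cat96, signatures = sig_res,
                 kataegis = kat, subtype = sub, comparisons = cmp,
                 manifest = manifest))
}

#' Render a markdown summary report from pipeline outputs
#'
#' Reassembles the numbers already written by [run_pipeline()] into a single
#' human-readable markdown file; every figure in the report is read back from
#' the machine-readable TSV/JSON outputs, never recomputed, so regenerating
#' the report cannot change any number. Sections whose stage output is
#' missing are skipped with a notice.
#'
#' @param outdir the pipeline output directory.
#' @param path report destination (default `report.md` inside `outdir`).
#' @return invisibly, the report path.
#' @export
render_report <- function(outdir, path = file.path(outdir, "report.md")) {
  L <- c("# flsubtype pipeline report", "")
  sec <- function(title, file, body) {
    f <- file.path(outdir, file)
    if (!file.exists(f)) {
      c(paste0("## ", title), "", paste0("_Skipped: missing ", file, "._"), "")
    } else c(paste0("## ", title), "", body(f), "")
  }
  L <- c(L, sec("Mutation catalog", "catalog.tsv", function(f) {
    m <- read_catalog(f)
    c(paste0("Samples: ", nrow(m), "; total SNVs: ", sum(m), "."),
      paste0("Top channel overall: ",
             sbs96_channels()[which.max(colSums(m))], "."))
  }))
  L <- c(L, sec("De-novo signatures", "signatures_denovo.tsv", function(f) {
    s <- read_signatures(f)
    paste0("Extracted ", ncol(s), " signature(s): ",
           paste(colnames(s), collapse = ", "), ".")
  }))
  L <- c(L, sec("Kataegis", "kataegis_events.tsv", function(f) {
    ev <- utils::read.delim(f)
    if (nrow(ev) == 0L) return("Zero kataegis events detected.")
    c(paste0(nrow(ev), " events across ", length(unique(ev$sample)),
             " sample(s); median members per event: ",
             stats::median(ev$n_mutations), "."),
      paste0("K1-dominant events: ",
             sum(ev$dominance == "K1-dominant", na.rm = TRUE), "."))
  }))
  L <- c(L, sec("Genetic subtypes", "clusters.json", function(f) {
    cl <- jsonlite::read_json(f, simplifyVector = TRUE)
    c(paste0("Selected K = ", cl$selected_k, "."),
      paste0("Cophenetic by K: ",
             paste(names(cl$cophenetic), round(unlist(cl$cophenetic), 3),
                   sep = "=", collapse = ", "), "."))
  }))
  L <- c(L, sec("Cluster markers", "marker_table.tsv", function(f) {
    mk <- utils::read.delim(f)
    paste0(sum(mk$assigned), " marker-cluster assignments at p <= 0.05.")
  }))
  L <- c(L, sec("Group comparisons", "group_comparisons.tsv", function(f) {
    gc <- utils::read.delim(f)
    vapply(seq_len(nrow(gc)), function(i) {
      paste0(gc$variable[i], ": ", gc$test[i], " p = ",
             signif(gc$p[i], 3), ".")
    }, character(1))
  }))
  writeLines(L, path)
  invisible(path)
}
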