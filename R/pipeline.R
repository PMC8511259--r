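#' Default pipeline configuration
#'
#' Flat key namespace, one entry per tunable threshold surfaced by the
#' analysis modules, with the module defaults.  Vector-valued entries are
#' comma-separated strings in the config file.
#'
#' @return named list of defaults
#' @export
default_config <- function() {
  list(
    seed = 1,
    stages = "simulate,qc,structure,fstats,roh,ylineage,imputeval",
    sim.k = 3, sim.n_sites = 4000,
    sim.drift = "0.05,0.1,0.15",
    sim.group_sizes = "30,30,30",
    sim.alpha_own = 5, sim.alpha_other = 0.2,
    sim.missing_rate = 0.002,
    sim.roh_per_sample = 2, sim.roh_min_bp = 1e6, sim.roh_max_bp = 8e6,
    sim.roh_het_error = 0.002,
    qc.total_missingness_max = 0.05, qc.per_chrom_missingness_max = 0.20,
    qc.sd_multiplier = 3,
    qc.max_missingness = 0.01, qc.min_minor_allele_count = 3,
    qc.hwe_p_threshold = 1e-5,
    structure.r2_max = 0.2, structure.window_snps = 50,
    structure.step_snps = 5, structure.n_pcs = 5,
    structure.dominance_threshold = 0.5,
    fstats.block_size_bp = 5e6,
    roh.het_error = 0.001, roh.az_mean_bp = 1e6, roh.hw_mean_bp = 1e7,
    roh.quality_min = 50,
    ylineage.n_clusters = 4, ylineage.cluster_size = 12,
    ylineage.depth_years = 12000,
    ylineage.min_support = 0.9, ylineage.large_min = 10,
    ylineage.mu = 0.76e-9, ylineage.region_len_bp = 1e7,
    ylineage.years_per_generation = 30,
    impute.n_ref = 60, impute.n_target = 20, impute.array_fraction = 0.3
  )
}

num_vec <- function(x) as.numeric(strsplit(as.character(x), ",")[[1]])

#' Parse a plain-text pipeline configuration
#'
#' One `key = value` pair per line; `#` starts a comment.  Unknown keys are
#' rejected before any computation.  Values are coerced to the type of the
#' corresponding default.
#'
#' @param path config file (NULL = pure defaults)
#' @param overrides named list applied after the file
#' @return full configuration list
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  set_key <- function(key, val) {
    if (!key %in% names(cfg))
      stop("unknown config key: ", key)
    cfg[[key]] <<- if (is.numeric(cfg[[key]])) as.numeric(val)
                   else as.character(val)
  }
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop("malformed config line: ", ln)
      set_key(trimws(kv[1]), trimws(kv[2]))
    }
  }
  for (k in names(overrides)) set_key(k, overrides[[k]])
  cfg
}

write_config <- function(cfg, path) {
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, as.character, "")), path)
  invisible(path)
}

log_line <- function(log, stage, msg, ...) {
  entry <- list(stage = stage, time = format(Sys.time(), "%H:%M:%S"),
                message = sprintf(msg, ...))
  message(sprintf("[%s] %s: %s", entry$time, stage, entry$message))
  c(log, list(entry))
}

#' Run the pipeline end to end on a synthetic cohort
#'
#' Executes the enabled stages in order simulate -> qc -> structure ->
#' fstats -> roh -> ylineage -> imputeval, writing each stage's TSV
#' artifacts plus the echoed configuration and a machine-readable run log
#' into `out_dir`.  A stage failure halts the run naming the stage;
#' artifacts of completed stages are retained.
#'
#' @param config list from [parse_config()] (or [default_config()])
#' @param out_dir output directory
#' @return invisibly, a list with the in-memory stage results and the log
#' @export
run_pipeline <- function(config = default_config(),
                         out_dir = "arabpop_out") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "config_echo.txt"))
  seed <- config$seed
  stages <- strsplit(config$stages, ",")[[1]]
  log <- list()
  res <- list()
  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible())
    log <<- log_line(log, name, "started")
    out <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res[[name]] <<- out
    log <<- log_line(log, name, "done")
  }

  run_stage("simulate", function() {
    model <- ancestral_model(K = config$sim.k,
                             n_sites = config$sim.n_sites,
                             drift = num_vec(config$sim.drift),
                             seed = seed)
    sizes <- num_vec(config$sim.group_sizes)
    groups <- lapply(seq_len(config$sim.k), function(k) {
      alpha <- rep(config$sim.alpha_other, config$sim.k)
      alpha[k] <- config$sim.alpha_own
      list(n = sizes[min(k, length(sizes))], alpha = alpha)
    })
    names(groups) <- paste0("POP", seq_len(config$sim.k))
    cohort <- simulate_admixed_cohort(model, groups,
                                      missing_rate = config$sim.missing_rate)
    cohort <- plant_roh(cohort,
                        list(long = list(n = config$sim.roh_per_sample,
                                         min_bp = config$sim.roh_min_bp,
                                         max_bp = config$sim.roh_max_bp)),
                        het_error = config$sim.roh_het_error)
    write_vcf(cohort$genotypes, file.path(out_dir, "cohort.vcf"))
    write_truth_registries(cohort, out_dir)
    cohort
  })
  cohort <- res$simulate

  run_stage("qc", function() {
    sq <- sample_qc(cohort$genotypes,
                    total_missingness_max = config$qc.total_missingness_max,
                    per_chrom_missingness_max =
                      config$qc.per_chrom_missingness_max,
                    sd_multiplier = config$qc.sd_multiplier)
    write_tsv(sq$report, file.path(out_dir, "sample_qc.tsv"))
    g_kept <- subset_genotypes(cohort$genotypes, sq$retained)
    vf <- variant_filter(g_kept, variant_filter_spec(
      max_missingness = config$qc.max_missingness,
      min_minor_allele_count = config$qc.min_minor_allele_count,
      hwe_p_threshold = config$qc.hwe_p_threshold))
    write_tsv(data.frame(rule = names(vf$counts), excluded = vf$counts),
              file.path(out_dir, "variant_filter_counts.tsv"))
    write_vcf(vf$genotypes, file.path(out_dir, "cohort_filtered.vcf"))
    list(sample_qc = sq, variant_filter = vf)
  })
  g_clean <- if (!is.null(res$qc)) res$qc$variant_filter$genotypes
             else cohort$genotypes

  run_stage("structure", function() {
    pruned_idx <- ld_prune(g_clean, r2_max = config$structure.r2_max,
                           window_snps = config$structure.window_snps,
                           step_snps = config$structure.step_snps)
    g_pruned <- subset_genotypes(g_clean, sites = pruned_idx)
    pc <- pca_genotypes(g_pruned, n_components = config$structure.n_pcs)
    write_tsv(data.frame(sample = rownames(pc$scores), pc$scores),
              file.path(out_dir, "pca_scores.tsv"))
    q <- q_matrix(cohort$true_Q)
    asg <- assign_dominant_ancestry(
      q, threshold = config$structure.dominance_threshold)
    write_tsv(asg, file.path(out_dir, "ancestry_assignment.tsv"))
    list(pruned = pruned_idx, pca = pc, assignment = asg)
  })

  run_stage("fstats", function() {
    ft <- site_freq_table(g_clean)
    pops <- colnames(ft$ac)
    pairs <- utils::combn(pops, 2, simplify = FALSE)
    fst_rows <- lapply(pairs, function(pr) {
      f <- fst_pairwise(ft, pr[1], pr[2])
      data.frame(pop1 = pr[1], pop2 = pr[2], fst = f$fst,
                 n_sites = f$n_sites)
    })
    write_tsv(do.call(rbind, fst_rows), file.path(out_dir, "fst.tsv"))
    f3s <- list()
    if (length(pops) >= 3L) {
      for (cc in pops) {
        srcs <- setdiff(pops, cc)
        for (pr in utils::combn(srcs, 2, simplify = FALSE)) {
          f3s[[length(f3s) + 1L]] <-
            f3_statistic(ft, pr[1], pr[2], cc,
                         block_size_bp = config$fstats.block_size_bp)
        }
      }
      f3_tab <- do.call(rbind, lapply(f3s, function(r)
        data.frame(A = r$populations[["A"]], B = r$populations[["B"]],
                   C = r$populations[["C"]], f3 = r$statistic, se = r$se,
                   z = r$z, blocks = r$n_blocks, sites = r$n_sites)))
      write_tsv(f3_tab, file.path(out_dir, "f3.tsv"))
      net <- build_admixture_network(f3s)
      write_tsv(net$edges, file.path(out_dir, "admixture_network.tsv"))
    }
    list(freq_table = ft, f3 = f3s)
  })

  run_stage("roh", function() {
    segs <- call_roh(g_clean, roh_params(
      het_error = config$roh.het_error,
      az_mean_bp = config$roh.az_mean_bp,
      hw_mean_bp = config$roh.hw_mean_bp,
      quality_min = config$roh.quality_min))
    pm <- stats::setNames(g_clean$pop, rownames(g_clean$geno))
    cls <- if (nrow(segs)) fit_roh_classes(segs, pm, seed = seed)
           else list(segments = segs, models = list())
    write_tsv(cls$segments, file.path(out_dir, "roh_segments.tsv"))
    fi <- inbreeding_f(g_clean)
    write_tsv(fi, file.path(out_dir, "inbreeding.tsv"))
    sm <- if (nrow(segs)) roh_summaries(cls$segments) else NULL
    if (!is.null(sm))
      write_tsv(sm$class_summary, file.path(out_dir, "roh_summary.tsv"))
    list(segments = cls$segments, models = cls$models, inbreeding = fi)
  })

  run_stage("ylineage", function() {
    yl <- simulate_y_locus(
      n_clusters = config$ylineage.n_clusters,
      sizes = config$ylineage.cluster_size,
      mu = config$ylineage.mu,
      region_len_bp = config$ylineage.region_len_bp,
      depth_years = config$ylineage.depth_years, seed = seed)
    write_vcf(yl$haplotypes, file.path(out_dir, "ylocus.vcf"))
    write_truth_registries(yl, out_dir)
    coll <- collapse_low_support(yl$tree,
                                 min_support = config$ylineage.min_support)
    sc <- scan_cutoffs(coll, large_min = config$ylineage.large_min)
    write_tsv(sc$tally, file.path(out_dir, "cutoff_tally.tsv"))
    sh <- informative_snps(yl$haplotypes, sc$clusters$clusters)
    ages <- date_lineages(sh, mu = config$ylineage.mu,
                          L = config$ylineage.region_len_bp,
                          g = config$ylineage.years_per_generation,
                          seed = seed)
    write_tsv(ages, file.path(out_dir, "subhaplogroups.tsv"))
    list(locus = yl, scan = sc, subhaps = sh, ages = ages)
  })

  run_stage("imputeval", function() {
    sat <- saturation_curve(cohort$genotypes, n_permutations = 5,
                            seed = seed)
    write_tsv(data.frame(n_samples = seq_along(sat$mean_curve),
                         mean_variants = sat$mean_curve),
              file.path(out_dir, "saturation.tsv"))
    pp <- make_panel_pair(cohort, n_ref = config$impute.n_ref,
                          n_target = config$impute.n_target,
                          array_fraction = config$impute.array_fraction,
                          dir = out_dir)
    pa <- make_pseudo_array(pp$target, pp$manifest)
    af_panel <- allele_freq(subset_genotypes(pp$reference,
                                             sites = pa$withheld_idx))
    tabs <- lapply(c("freq", "nearest_haplotype"), function(meth) {
      imp <- impute_naive(pa$typed, pp$reference, pa$withheld_idx,
                          method = meth)
      tab <- aggregate_r2(pp$target, imp$dosage, imp$withheld_idx,
                          af_panel, quality = imp$quality)
      tab$method <- meth
      tab
    })
    write_tsv(do.call(rbind, tabs), file.path(out_dir, "imputation_r2.tsv"))
    list(saturation = sat, r2 = tabs)
  })

  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(res, list(log = log, out_dir = out_dir)))
}

#' Command-line entry point
#'
#' `arabpop <stage|all> [--config FILE] [--seed N] [--out DIR]` where stage
#' is one of simulate, qc, structure, fstats, roh, ylineage, imputeval.
#' Earlier stages a later stage depends on are run as well (the pipeline is
#' synthetic-data driven end to end).
#'
#' @param args character vector (default: command line)
#' @return exit status 0 invisibly
#' @export
arabpop_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages_all <- c("simulate", "qc", "structure", "fstats", "roh",
                  "ylineage", "imputeval")
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat("usage: arabpop <", paste(c(stages_all, "all"), collapse = "|"),
        "> [--config FILE] [--seed N] [--out DIR]\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  if (!cmd %in% c(stages_all, "all")) stop("unknown command: ", cmd)
  opt <- list(config = NULL, seed = NULL, out = "arabpop_out")
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option: ", args[i])
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  overrides <- list()
  if (cmd != "all") {
    need <- stages_all[seq_len(match(cmd, stages_all))]
    overrides$stages <- paste(need, collapse = ",")
  }
  if (!is.null(opt$seed)) overrides$seed <- as.numeric(opt$seed)
  cfg <- parse_config(opt$config, overrides)
  run_pipeline(cfg, out_dir = opt$out)
  invisible(0L)
}
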