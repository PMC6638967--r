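# End-to-end orchestration: simulate -> correct phenotypes -> reconstruct
# IBD -> phase -> scan -> QTL/FDR -> variance components, from one config
# with a single root seed.

#' Pipeline configuration
#'
#' All tunables of an end-to-end run.  The defaults are a desk-scale
#' analogue of the full design (fewer families, a shrunken genome) so a run
#' completes in minutes; `famlink` functions accept the full-scale geometry
#' through the same fields.  A YAML file with any subset of the fields can
#' be supplied instead.
#'
#' @param yaml optional path to a YAML file of overrides.
#' @param ... named overrides (take precedence over the YAML).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(yaml = NULL, ...) {
  cfg <- list(
    n_families = 12L, sib_range = c(10L, 20L), mean_sibs = 12,
    n_chrom = 4L, total_bp = 6e7, total_morgans = 6, n_snps = 6000L,
    n_haplotypes = 120L, n_elevated = 40L,
    causal = data.frame(snp = character(0), beta = numeric(0)),
    n_causal = 3L, causal_beta = 0.45, h2_total = 0.86, shared_env = 0,
    noise = TRUE, parents_genotyped = TRUE,
    grid_step = 5e4, n_perm = 200L,
    lod_thresholds = seq(3.6, 1.0, by = -0.1),
    merge_distance_scale = TRUE,
    reference_phasing = FALSE,
    run_varcomp = TRUE, run_crossval = FALSE,
    cv_splits = 3L, cv_random = 3L
  )
  if (!is.null(yaml)) {
    over <- yaml::read_yaml(yaml)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

.substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  (as.integer(seed) + h) %% .Machine$integer.max
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order, writes all stage outputs under
#' `out_dir` as plain text, and finishes with a manifest (file list, md5
#' hashes, config hash).  Reruns with the same config and seed are
#' bit-identical.
#'
#' @param config `pipeline_config`.
#' @param out_dir output directory (created).
#' @param seed integer root seed; every stage derives a named substream.
#' @param quiet suppress progress messages.
#' @return invisibly a list with the main in-memory results (`cohort`,
#'   `scan`, `qtls`, `fdr`, `h2`, paths, manifest).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed,
                         quiet = FALSE) {
  if (missing(seed)) stop("'seed' is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- simulate ------------------------------------------------------------
  say("[simulate] cohort geometry: %d families, %d chromosomes, %d SNPs",
      config$n_families, config$n_chrom, config$n_snps)
  sim <- stage("simulate", {
    map <- scaled_genome(config$total_bp, config$total_morgans, config$n_chrom)
    snps <- place_snps(map, config$n_snps)
    pool <- simulate_founder_pool(snps, config$n_haplotypes,
                                  n_elevated = config$n_elevated,
                                  seed = .substream(seed, "pool"))
    ped <- make_cohort_pedigree(config$n_families, config$sib_range,
                                config$mean_sibs,
                                parents_genotyped = config$parents_genotyped,
                                seed = .substream(seed, "pedigree"))
    fam <- simulate_families(ped, pool, map, seed = .substream(seed, "families"))
    causal <- config$causal
    if (nrow(causal) == 0 && config$n_causal > 0) {
      set.seed(.substream(seed, "causal"))
      csnp <- sample(snps$snp[pool$elevated], config$n_causal)
      causal <- data.frame(snp = csnp, beta = config$causal_beta)
    }
    model <- phenotype_model(h2_total = config$h2_total, causal = causal,
                             shared_env = config$shared_env)
    pheno <- simulate_phenotypes(ped, fam$geno, model,
                                 seed = .substream(seed, "phenotypes"),
                                 freqs = pool$pool_freq)
    geno_obs <- if (isTRUE(config$noise)) {
      apply_genotyping_noise(fam$geno, noise_model(),
                             seed = .substream(seed, "noise"))
    } else fam$geno
    list(map = map, snps = snps, pool = pool, ped = ped, truth = fam$truth,
         geno_clean = fam$geno, geno = geno_obs, pheno = pheno, model = model,
         causal = causal)
  })
  write_tsv(sim$pheno, file.path(out_dir, "phenotypes_raw.tsv"))
  write_ped_map(sim$geno, sim$ped, file.path(out_dir, "genotypes"))

  # --- phenotype correction ------------------------------------------------
  corr <- stage("phenotype", correct_heights(sim$pheno))
  write_tsv(corr, file.path(out_dir, "phenotypes_corrected.tsv"))
  z <- stats::setNames(corr$z, corr$iid)

  # --- IBD reconstruction --------------------------------------------------
  say("[ibd] reconstructing %d families", length(family_ids(sim$ped)))
  recon <- stage("ibd", {
    lapply(stats::setNames(nm = family_ids(sim$ped)), function(f) {
      reconstruct_family_ibd(sim$geno, sim$ped, f, sim$map)
    })
  })
  vectors_list <- lapply(recon, `[[`, "vectors")
  shr <- ibd_sharing_summary(unlist(lapply(vectors_list, function(v) {
    family_pair_tracks(v)
  }), recursive = FALSE))
  write_tsv(data.frame(shared = 0:2, fraction = as.numeric(shr)),
            file.path(out_dir, "ibd_sharing.tsv"))
  say("[ibd] genome shared 0/1/2: %.1f%% / %.1f%% / %.1f%%",
      100 * shr[1], 100 * shr[2], 100 * shr[3])

  # --- phasing -------------------------------------------------------------
  phased <- stage("phase", {
    lapply(family_ids(sim$ped), function(f) {
      phase_family(sim$geno, vectors_list[[f]], sim$ped, f)
    })
  })
  names(phased) <- family_ids(sim$ped)
  if (isTRUE(config$reference_phasing)) {
    phased <- stage("phase_reference", {
      lapply(phased, function(ph) {
        panel <- build_reference_panel(phased, nrow(sim$snps), exclude_fid = ph$fid)
        phase_with_reference(ph, panel, sim$snps)
      })
    })
  }
  geno_inf <- inferred_genotypes(phased, sim$geno)
  qc <- lapply(family_ids(sim$ped), function(f) {
    phasing_qc(sim$geno, phased[[f]], vectors_list[[f]])
  })
  qc_tab <- data.frame(
    fid = family_ids(sim$ped),
    rate_all = vapply(qc, `[[`, numeric(1), "rate_all"),
    rate_hq = vapply(qc, `[[`, numeric(1), "rate_hq"),
    completeness = vapply(phased, phase_completeness, numeric(1)))
  write_tsv(qc_tab, file.path(out_dir, "phasing_qc.tsv"))

  # --- linkage scan --------------------------------------------------------
  say("[scan] %d permutations on a %.0f kb grid", config$n_perm,
      config$grid_step / 1000)
  scan <- stage("scan", {
    cohort_scan(vectors_list, z, sim$map, config$grid_step, config$n_perm,
                seed = .substream(seed, "scan"))
  })
  write_tsv(data.frame(scan$grid, score = scan$score, gw_p = scan$gw_p,
                       lod = scan$lod),
            file.path(out_dir, "scan.tsv"))

  merge_d <- if (isTRUE(config$merge_distance_scale)) {
    33e6 * sum(sim$map$length) / 2.88e9
  } else 33e6
  qtls <- stage("qtl", call_qtls(scan, utils::tail(config$lod_thresholds, 1), merge_d))
  fdr <- stage("fdr", fdr_sweep(scan, config$lod_thresholds, merge_d))
  write_tsv(qtls, file.path(out_dir, "qtls.tsv"))
  write_tsv(fdr, file.path(out_dir, "fdr_sweep.tsv"))

  # --- variance components -------------------------------------------------
  h2 <- NULL
  if (isTRUE(config$run_varcomp)) {
    h2 <- stage("varcomp", {
      A <- kinship_from_pedigree(sim$ped)
      pedigree_heritability(corr, A)
    })
    write_tsv(data.frame(h2 = h2$h2, se = h2$se),
              file.path(out_dir, "heritability.tsv"))
    say("[varcomp] pedigree h2 = %.2f (SE %.2f)", h2$h2, h2$se)
  }
  cv <- NULL
  if (isTRUE(config$run_crossval)) {
    cv <- stage("crossval", {
      design <- cv_design(sim$ped, config$cv_splits,
                          seed = .substream(seed, "cv"))
      cohort <- list(ped = sim$ped, geno = geno_inf,
                     vectors_list = vectors_list, heights = z, map = sim$map)
      cross_validate_variance(cohort, design, thresholds = c(2.0, 1.5),
                              n_random = config$cv_random,
                              n_perm = max(100L, config$n_perm %/% 2),
                              grid_step = config$grid_step,
                              seed = .substream(seed, "cv_fit"))
    })
    write_tsv(as.data.frame(cv), file.path(out_dir, "cv_variance.tsv"))
  }

  # --- manifest ------------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"))
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = seed,
    files = lapply(stats::setNames(nm = files), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("[done] %d output files in %s", length(files), out_dir)
  invisible(list(cohort = sim, corrected = corr, recon = recon, phased = phased,
                 geno_inferred = geno_inf, scan = scan, qtls = qtls, fdr = fdr,
                 h2 = h2, cv = cv, manifest = manifest, out_dir = out_dir))
}
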