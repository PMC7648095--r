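pipeline_defaults <- function() {
  list(
    seed = 1L,
    donor = "G1",
    sex = "female",
    stages = c("screen", "damage", "sex", "f3", "consensus", "place"),
    n_reads = 20000L,
    endogenous_frac = 0.6,
    mean_len = 59, len_sd = 12, min_len = 30,
    damage_p0 = 0.10, damage_lambda = 0.3,
    panel = list(n_genomes = 3L, chrX_len = 50000L, autosome_len = 54000L,
                 divergence = 0.05),
    mito = list(n_clades = 4L, haplotypes_per_clade = 4L, length = 16000L,
                between_clade_div = 0.05, within_clade_div = 0.005,
                donor_clade = 2L, depth = 3),
    mapping = list(k = 16L, stride = 4L, max_mismatch_frac = 0.015,
                   damage_max_mismatch_frac = 0.1,
                   score_gap = 4, mismatch_penalty = 2),
    screen = list(min_margin = 2),
    sex_call = list(female_min = 0.8, male_max = 0.6, min_total = 200),
    f3 = list(block_size = 5000, n_panel = 10L, within_div = 0.01,
              transversions_only = TRUE, z_threshold = -3),
    consensus = list(depths = c(1, 3)),
    placement = list(model = "K2P", replicates = 100L)
  )
}

# recursive defaults merge collecting unknown-key and range errors
merge_config <- function(user, defaults, path, errors) {
  for (k in names(user)) {
    if (!k %in% names(defaults)) {
      known <- names(defaults)
      d <- utils::adist(k, known)
      hint <- if (min(d) <= 3)
        paste0(" - did you mean '", known[which.min(d)], "'?") else ""
      errors$msgs <- c(errors$msgs,
                       paste0("unknown key '", paste(c(path, k),
                                                     collapse = "."), "'",
                              hint))
    } else if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(as.list(user[[k]]), defaults[[k]],
                                    c(path, k), errors)
    } else {
      defaults[[k]] <- if (is.list(user[[k]])) unlist(user[[k]])
                       else user[[k]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Fills documented defaults, rejects unknown keys (with a nearest-match
#' suggestion), and checks value ranges. All violations are reported
#' together.
#'
#' @param config a named list, or the path to a JSON file.
#' @return the normalized configuration (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  stopifnot(is.list(config))
  errors <- new.env()
  errors$msgs <- character(0)
  cfg <- merge_config(config, pipeline_defaults(), character(0), errors)

  chk <- function(cond, msg) if (!isTRUE(cond))
    errors$msgs <- c(errors$msgs, msg)
  chk(cfg$endogenous_frac >= 0 && cfg$endogenous_frac <= 1,
      "endogenous_frac must lie in [0, 1]")
  chk(cfg$damage_p0 >= 0 && cfg$damage_p0 <= 1,
      "damage_p0 must lie in [0, 1]")
  chk(cfg$damage_lambda >= 0, "damage_lambda must be >= 0")
  chk(cfg$n_reads >= 1, "n_reads must be positive")
  chk(cfg$min_len >= 1 && cfg$mean_len >= cfg$min_len,
      "need mean_len >= min_len >= 1")
  chk(cfg$sex %in% c("female", "male"), "sex must be 'female' or 'male'")
  chk(all(cfg$stages %in% pipeline_defaults()$stages),
      paste0("stages must be a subset of: ",
             paste(pipeline_defaults()$stages, collapse = ", ")))
  chk(cfg$panel$divergence >= 0 && cfg$panel$divergence < 0.75,
      "panel.divergence must lie in [0, 0.75)")
  chk(cfg$panel$n_genomes >= 2, "panel.n_genomes must be at least 2")
  chk(cfg$mito$n_clades >= 2, "mito.n_clades must be at least 2")
  chk(cfg$mito$donor_clade >= 1 &&
        cfg$mito$donor_clade <= cfg$mito$n_clades,
      "mito.donor_clade must name one of the clades")
  chk(cfg$mito$n_clades >= cfg$panel$n_genomes,
      "mito.n_clades must be >= panel.n_genomes (one mitogenome per taxon)")
  chk(cfg$mapping$k >= 8 && cfg$mapping$k <= 32,
      "mapping.k must lie in [8, 32]")
  chk(cfg$mapping$max_mismatch_frac >= 0 &&
        cfg$mapping$max_mismatch_frac < 1,
      "mapping.max_mismatch_frac must lie in [0, 1)")
  chk(cfg$placement$model %in% c("K2P", "p"),
      "placement.model must be 'K2P' or 'p'")
  chk(cfg$placement$replicates >= 1, "placement.replicates must be >= 1")
  if (length(errors$msgs))
    stop("invalid configuration:\n  - ",
         paste(errors$msgs, collapse = "\n  - "), call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full specimen-identification pipeline on synthetic data
#'
#' Orchestrates simulate -> map -> screen -> damage -> sex -> f3 ->
#' consensus -> place with one configuration and one master seed. Every
#' stage draws its randomness from a seed derived from the master seed and
#' the stage name, so re-running any subset reproduces the same results.
#' Omitted stages are marked `"skipped"` in the report. A stage failure
#' halts the run with the stage name after preserving the partial report.
#'
#' @param config configuration list or JSON path, see [validate_config()].
#' @param out_dir optional run directory; per-stage outputs, a JSON report
#'   and a text summary are written there.
#' @return an object of class `specimen_report`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- validate_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  logit <- function(stage, event) {
    line <- sprintf("[%s] %s", stage, event)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  report <- list(
    config = unclass(cfg),
    truth = list(donor = cfg$donor, sex = cfg$sex,
                 clade = paste0("clade", cfg$mito$donor_clade)),
    species = "skipped", conplastic = "skipped", damage = "skipped",
    sex = "skipped", f3 = "skipped", consensus = "skipped",
    placement = "skipped")
  finalize <- function(report, failed_stage = NULL, err = NULL) {
    report$provenance <- list(
      package = "skimprov",
      version = as.character(utils::packageVersion("skimprov")),
      seed = cfg$seed,
      failed_stage = failed_stage, error = err)
    class(report) <- "specimen_report"
    if (!is.null(out_dir)) {
      jsonlite::write_json(unclass(report),
                           file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
      writeLines(log_lines, file.path(out_dir, "run.log"))
      writeLines(utils::capture.output(print(report)),
                 file.path(out_dir, "report.txt"))
    }
    report
  }
  stage <- "simulate"
  res <- tryCatch({
    # ---- simulate: panels, reads ------------------------------------
    logit(stage, "building reference panel and clade panel")
    ng <- cfg$panel$n_genomes
    dv <- matrix(cfg$panel$divergence, ng, ng)
    diag(dv) <- 0
    nuc_panel <- make_reference_panel(
      base_length = cfg$panel$chrX_len, n_genomes = ng,
      divergence_matrix = dv, seed = derive_seed(cfg$seed, "panel"),
      seq_lengths = c(chrX = cfg$panel$chrX_len,
                      chr8 = cfg$panel$autosome_len))
    clade_panel <- make_clade_panel(
      n_clades = cfg$mito$n_clades,
      haplotypes_per_clade = cfg$mito$haplotypes_per_clade,
      between_clade_div = cfg$mito$between_clade_div,
      within_clade_div = cfg$mito$within_clade_div,
      length = cfg$mito$length, seed = derive_seed(cfg$seed, "mito_panel"))
    # one species-level mitogenome per nuclear genome: the donor genome
    # carries the donor clade's first haplotype, the others take the
    # remaining clades' first haplotypes
    donor_clade <- paste0("clade", cfg$mito$donor_clade)
    clade_order <- c(cfg$mito$donor_clade,
                     setdiff(seq_len(cfg$mito$n_clades),
                             cfg$mito$donor_clade))
    mt_refs <- lapply(clade_order[seq_len(ng)], function(ci)
      c(mt = unname(clade_panel$alignment[sprintf("clade%d_h1", ci)])))
    names(mt_refs) <- names(nuc_panel$genomes)
    mito_panel <- reference_panel(mt_refs)

    logit(stage, sprintf("simulating %d nuclear reads (%s, %s)",
                         cfg$n_reads, cfg$donor, cfg$sex))
    cn <- if (cfg$sex == "male") c(chrX = 0.5) else NULL
    nuc_cfg <- simulation_config(
      seed = derive_seed(cfg$seed, "reads_nuclear"), n_reads = cfg$n_reads,
      mean_len = cfg$mean_len, len_sd = cfg$len_sd, min_len = cfg$min_len,
      endogenous_frac = cfg$endogenous_frac, damage_p0 = cfg$damage_p0,
      damage_lambda = cfg$damage_lambda, copy_number = cn)
    nuc_reads <- simulate_reads(nuc_panel, cfg$donor, nuc_cfg)
    n_mt <- max(50L, round(cfg$mito$depth * cfg$mito$length / cfg$mean_len))
    logit(stage, sprintf("simulating %d mitochondrial reads (~%gX)",
                         n_mt, cfg$mito$depth))
    mt_cfg <- simulation_config(
      seed = derive_seed(cfg$seed, "reads_mito"), n_reads = n_mt,
      mean_len = cfg$mean_len, len_sd = cfg$len_sd, min_len = cfg$min_len,
      endogenous_frac = 1, damage_p0 = cfg$damage_p0,
      damage_lambda = cfg$damage_lambda)
    mt_reads <- simulate_reads(mito_panel, cfg$donor, mt_cfg)
    if (!is.null(out_dir)) {
      write_fastq(nuc_reads, file.path(out_dir, "reads_nuclear.fastq"))
      write_truth(nuc_reads, file.path(out_dir, "reads_nuclear.truth.tsv"))
      write_fastq(mt_reads, file.path(out_dir, "reads_mito.fastq"))
    }

    # ---- map ---------------------------------------------------------
    stage <- "map"
    logit(stage, "mapping nuclear reads against the panel")
    mp <- cfg$mapping
    nuc_idx <- build_index(nuc_panel, k = mp$k)
    nuc_map <- map_reads(nuc_reads, nuc_idx,
                         max_mismatch_frac = mp$max_mismatch_frac,
                         score_gap = mp$score_gap,
                         mismatch_penalty = mp$mismatch_penalty,
                         stride = mp$stride)
    logit(stage, "mapping mitochondrial reads against the mitogenomes")
    mt_idx <- build_index(mito_panel, k = mp$k)
    mt_map <- map_reads(mt_reads, mt_idx,
                        max_mismatch_frac = mp$max_mismatch_frac,
                        score_gap = mp$score_gap,
                        mismatch_penalty = mp$mismatch_penalty,
                        stride = mp$stride)

    # ---- screen ------------------------------------------------------
    nuclear_genome <- cfg$donor   # fallback when screen is skipped
    mito_genome <- cfg$donor
    runner_up <- setdiff(names(nuc_panel$genomes), cfg$donor)[1]
    if ("screen" %in% cfg$stages) {
      stage <- "screen"
      logit(stage, "species screen, nuclear and mitochondrial")
      nuc_tab <- screen_reads(nuc_map)
      nuc_asg <- assign_species(nuc_tab, cfg$screen$min_margin)
      mt_tab <- screen_reads(mt_map)
      mt_asg <- assign_species(mt_tab, cfg$screen$min_margin)
      con <- conplastic_check(nuc_asg, mt_asg)
      if (nuc_asg$assigned != "ambiguous") {
        nuclear_genome <- nuc_asg$assigned
        runner_up <- setdiff(nuc_asg$ranking$genome, nuclear_genome)[1]
      }
      if (mt_asg$assigned != "ambiguous") mito_genome <- mt_asg$assigned
      report$species <- list(
        assigned = nuc_asg$assigned, margin = nuc_asg$margin,
        min_margin = nuc_asg$min_margin,
        one_genome_only = stats::setNames(nuc_tab$pct_one_genome_only,
                                          nuc_tab$genome),
        mito_assigned = mt_asg$assigned)
      report$conplastic <- con
      logit(stage, sprintf("nuclear -> %s (margin %.2f), mito -> %s (%s)",
                           nuc_asg$assigned, nuc_asg$margin,
                           mt_asg$assigned, con$status))
    }

    # unique deduplicated hits on the assigned nuclear genome feed the
    # damage, sex and f3 stages
    nuc_dd <- remove_duplicates(unique_hits(nuc_map, nuclear_genome))$hits

    if ("damage" %in% cfg$stages) {
      stage <- "damage"
      logit(stage, "estimating terminal deamination profile")
      # the strict screening budget censors reads with terminal damage, so
      # the damage profile uses a permissive remapping of the same reads
      dmg_map <- map_reads(nuc_reads, nuc_idx,
                           max_mismatch_frac = mp$damage_max_mismatch_frac,
                           score_gap = mp$score_gap,
                           mismatch_penalty = mp$mismatch_penalty,
                           stride = mp$stride)
      dmg_dd <- remove_duplicates(unique_hits(dmg_map, nuclear_genome))$hits
      prof <- estimate_damage(dmg_dd, nuc_reads, nuc_panel, nuclear_genome)
      auth <- authenticate_damage(prof)
      report$damage <- list(
        verdict = auth$verdict, checks = as.list(auth$checks),
        terminal_ct = prof$five_prime$freq[1],
        terminal_ga = prof$three_prime$freq[1],
        mean_length = prof$length_stats$mean,
        background_rate = prof$background_rate)
      logit(stage, sprintf("5' C->T at position 0: %.3f -> %s",
                           prof$five_prime$freq[1], auth$verdict))
    }

    if ("sex" %in% cfg$stages) {
      stage <- "sex"
      logit(stage, "genetic sex from the X/autosome read ratio")
      sx <- sex_from_mapping(nuc_map, nuc_panel, nuclear_genome,
                             "chrX", "chr8",
                             female_min = cfg$sex_call$female_min,
                             male_max = cfg$sex_call$male_max,
                             min_total = cfg$sex_call$min_total)
      report$sex <- list(call = sx$call, ratio = sx$ratio,
                         reads_x = sx$reads_x, reads_a = sx$reads_a,
                         thresholds = as.list(sx$thresholds))
      logit(stage, sprintf("ratio %.3f -> %s", sx$ratio, sx$call))
    }

    if ("f3" %in% cfg$stages) {
      stage <- "f3"
      logit(stage, sprintf("f3(%s; %s, %s) with block jackknife",
                           "specimen", nuclear_genome, runner_up))
      calls <- list()
      for (s in names(nuc_panel$genomes[[nuclear_genome]])) {
        pu <- build_pileup(nuc_dd, nuc_reads,
                           nuc_panel$genomes[[nuclear_genome]][[s]], s)
        calls[[s]] <- pseudo_haploidize(
          pu, seed = derive_seed(cfg$seed, paste0("haploidize_", s)))
      }
      f3r <- f3_specimen_test(
        nuc_panel, nuclear_genome, runner_up, calls,
        n_panel = cfg$f3$n_panel, within_div = cfg$f3$within_div,
        block_size_bp = cfg$f3$block_size,
        transversions_only = cfg$f3$transversions_only,
        z_threshold = cfg$f3$z_threshold,
        seed = derive_seed(cfg$seed, "f3_panels"))
      report$f3 <- list(verdict = f3r$verdict$verdict,
                        f3 = f3r$result$f3, Z = f3r$result$Z,
                        n_sites = f3r$result$n_sites,
                        n_blocks = f3r$result$n_blocks,
                        filter = f3r$result$filter)
      logit(stage, sprintf("f3 = %.6g, Z = %.3f -> %s", f3r$result$f3,
                           f3r$result$Z, f3r$verdict$verdict))
    }

    cons <- NULL
    if (any(c("consensus", "place") %in% cfg$stages)) {
      stage <- "consensus"
      logit(stage, "mitogenome pileup and depth-masked consensus")
      mt_dd <- remove_duplicates(unique_hits(mt_map, mito_genome))$hits
      mt_ref <- mito_panel$genomes[[mito_genome]][["mt"]]
      mt_pu <- build_pileup(mt_dd, mt_reads, mt_ref, "mt")
      fasta <- if (!is.null(out_dir))
        file.path(out_dir, "consensus_mt.fasta") else NULL
      cons <- consensus_report(mt_pu, depths = cfg$consensus$depths,
                               fasta = fasta, name = "specimen_mt")
      if ("consensus" %in% cfg$stages) {
        report$consensus <- list(mean_depth = cons$mean_depth,
                                 pct_zero = cons$pct_zero,
                                 by_depth = cons$by_depth)
        logit(stage, sprintf(
          "mean depth %.2fX; %%N: %s", cons$mean_depth,
          paste(sprintf("d%d=%.2f%%", cons$by_depth$min_depth,
                        cons$by_depth$pct_N), collapse = ", ")))
      }
    }

    if ("place" %in% cfg$stages) {
      stage <- "place"
      logit(stage, "neighbor-joining placement with bootstrap")
      strictest <- which.max(cfg$consensus$depths)
      query <- cons$consensus[[strictest]]$seq
      pl <- place_query(clade_panel, query, query_name = "specimen",
                        model = cfg$placement$model,
                        replicates = cfg$placement$replicates,
                        seed = derive_seed(cfg$seed, "bootstrap"))
      report$placement <- list(clade = pl$clade, support = pl$support,
                               query_missing_frac =
                                 cons$consensus[[strictest]]$missing_frac,
                               newick = pl$newick)
      logit(stage, sprintf("assigned %s (support %s)", pl$clade,
                           format(round(pl$support))))
    }
    finalize(report)
  }, error = function(e) {
    logit(stage, paste("FAILED:", conditionMessage(e)))
    finalize(report, failed_stage = stage, err = conditionMessage(e))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' @export
print.specimen_report <- function(x, ...) {
  cat("== specimen report (seed ", x$provenance$seed, ") ==\n", sep = "")
  fmt_stage <- function(name, val, fmt_fun) {
    if (identical(val, "skipped")) cat(sprintf("%-11s skipped\n", name))
    else cat(sprintf("%-11s %s\n", name, fmt_fun(val)))
  }
  fmt_stage("species:", x$species, function(v)
    sprintf("%s (one-genome-only margin %.2f pp)", v$assigned, v$margin))
  fmt_stage("conplastic:", x$conplastic, function(v)
    sprintf("%s (nuclear %s / mito %s)", v$status, v$nuclear, v$mito))
  fmt_stage("damage:", x$damage, function(v)
    sprintf("%s (5' C->T %.3f, mean length %.1f bp)", v$verdict,
            v$terminal_ct, v$mean_length))
  fmt_stage("sex:", x$sex, function(v)
    sprintf("%s (ratio %.2f; X %d / autosome %d reads)", v$call, v$ratio,
            v$reads_x, v$reads_a))
  fmt_stage("f3:", x$f3, function(v)
    sprintf("%s (f3 = %.6g, Z = %.3f, %d sites)", v$verdict, v$f3, v$Z,
            v$n_sites))
  fmt_stage("consensus:", x$consensus, function(v)
    sprintf("mean depth %.2fX; %%N %s", v$mean_depth,
            paste(sprintf("d%d: %.2f%%", v$by_depth$min_depth,
                          v$by_depth$pct_N), collapse = ", ")))
  fmt_stage("placement:", x$placement, function(v)
    sprintf("%s (support %s, query %.1f%% missing)", v$clade,
            format(round(v$support)), 100 * v$query_missing_frac))
  invisible(x)
}
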