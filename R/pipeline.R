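default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "dms_run",
    gene = list(preset = "cas2"),
    n_clones = 2000L,
    effects = list(),
    screen = list(base_rate = 1e-5, n_cells = 2e8,
                  reads_per_barcode = 2L, seq_error_rate = 1e-3),
    sequencing = list(unselected_coverage = 1.5, selected_coverage = 3),
    pseudocount = 0.5,
    min_reads_per_barcode = 2L,
    top_k = 8L,
    assays = NULL)
}

check_config_keys <- function(config) {
  known <- names(default_run_config())
  extra <- setdiff(names(config), known)
  if (length(extra) > 0L)
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  invisible(config)
}

load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  check_config_keys(config)
  cfg <- default_run_config()
  for (k in names(config)) {
    # screen/sequencing merge field-wise; everything else (notably
    # 'gene' and 'effects') replaces the default wholesale
    cfg[[k]] <- if (k %in% c("screen", "sequencing") &&
                    is.list(config[[k]]))
      utils::modifyList(cfg[[k]], config[[k]]) else config[[k]]
  }
  cfg
}

resolve_gene <- function(gene, n_clones) {
  if (!is.null(gene$preset))
    return(dms_preset(gene$preset, n_clones = n_clones))
  if (!is.null(gene$fasta)) {
    if (!file.exists(gene$fasta))
      stop("config field 'gene.fasta' points to a missing file: ",
           gene$fasta)
    ref <- read_reference_fasta(gene$fasta)
    return(library_preset(gene$gene_id %||% ref$gene_id,
                          wt_codons = ref$wt_codons,
                          lambda_mut = gene$lambda_mut %||% 1.5,
                          n_clones = n_clones))
  }
  if (!is.null(gene$L))
    return(library_preset(gene$gene_id %||% "gene", L = gene$L,
                          lambda_mut = gene$lambda_mut %||% 1.5,
                          n_clones = n_clones))
  stop("config field 'gene' needs one of: 'preset', 'fasta', 'L'")
}

effects_from_config <- function(effects) {
  if (is.null(effects) || length(effects) == 0L) return(effect_table())
  df <- if (is.data.frame(effects)) effects else
    do.call(rbind, lapply(effects, as.data.frame))
  effect_table(df$position, df$aa, df$multiplier)
}

#' Run the full screen pipeline from a declarative configuration
#'
#' Executes simulate (library, selection, reads), process (barcode
#' grouping, consensus, codon counts), DMS statistics (RPM,
#' preferences, differential selection), site scoring and optional
#' assay simulations, writing every artifact plus a manifest (seeds,
#' parameters, package version) into `out_dir`.  Rerunning the same
#' configuration reproduces identical tables: every stage seed is
#' derived deterministically from the master seed via [child_seed()].
#'
#' @param config configuration list or path to a JSON file; unknown
#'   keys are rejected.  See `dmscreen:::default_run_config()` for the
#'   full set of fields and defaults.
#' @return Invisibly, a list with the main in-memory results and the
#'   run directory.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(cfg$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  preset <- stage("configure", resolve_gene(cfg$gene, cfg$n_clones))
  effects <- stage("configure", effects_from_config(cfg$effects))
  segments <- default_segments(preset$L)

  lib <- stage("simulate-library",
               simulate_clone_library(preset,
                                      seed = child_seed(cfg$seed, "library")))
  write_reference_fasta(preset, path("reference.fasta"))
  write_truth_table(lib, effects, path("truth.tsv"))
  write_tsv_(segments, path("segments.tsv"))
  qc <- library_qc(lib)

  scfg <- screen_config(base_rate = cfg$screen$base_rate,
                        n_cells = cfg$screen$n_cells,
                        reads_per_barcode = cfg$screen$reads_per_barcode,
                        seq_error_rate = cfg$screen$seq_error_rate,
                        seed = child_seed(cfg$seed, "selection"))
  screen <- stage("simulate-screen", simulate_selection(lib, effects, scfg))

  n_colonies <- sum(screen$selected)
  depth <- list(
    unselected = round(cfg$sequencing$unselected_coverage * cfg$n_clones),
    selected = round(cfg$sequencing$selected_coverage * max(n_colonies, 1L)))
  tables <- list()
  for (sample in c("unselected", "selected")) {
    scfg$seed <- child_seed(cfg$seed, paste0("reads-", sample))
    reads <- stage("simulate-reads",
                   simulate_reads(screen[[sample]], lib, scfg,
                                  segments = segments,
                                  n_molecules = depth[[sample]]))
    write_fastq(reads, path(paste0(sample, ".fastq")))
    groups <- stage("process-reads",
                    group_by_barcode(reads, cfg$min_reads_per_barcode))
    cons <- stage("process-reads", call_consensus(groups))
    tab <- stage("process-reads",
                 count_codons(cons, preset$wt_codons, segments,
                              sample_id = sample))
    write_codon_counts(tab, path(paste0("codon_counts_", sample, ".tsv")))
    tables[[sample]] <- tab
  }

  stats <- stage("dms-stats", {
    sel_aa <- aggregate_to_aa(to_rpm(tables$selected))
    unsel_aa <- aggregate_to_aa(to_rpm(tables$unselected))
    enr <- enrichment(sel_aa, unsel_aa, cfg$pseudocount)
    prefs <- preferences(enr)
    dsel <- differential_selection(sel_aa, unsel_aa,
                                   pseudocount = cfg$pseudocount)
    write_site_matrix(prefs, path("preferences.tsv"))
    write_site_matrix(dsel, path("diffsel.tsv"), value = "diffsel")
    write_site_matrix(dsel, path("diffsel_matrix.tsv"), layout = "wide")
    list(preferences = prefs, diffsel = dsel)
  })

  scores <- stage("score-sites", score_sites(stats$preferences,
                                             stats$diffsel))
  top <- stage("score-sites",
               select_top_substitutions(scores, stats$diffsel, cfg$top_k))
  write_site_scores(scores, stats$diffsel, path("site_scores.tsv"))
  write_tsv_(top, path("top_substitutions.tsv"))

  assays <- NULL
  if (!is.null(cfg$assays))
    assays <- stage("assay", run_assays(cfg$assays,
                                        child_seed(cfg$seed, "assays"),
                                        cfg$out_dir))

  manifest <- list(
    package = "dmscreen",
    version = as.character(utils::packageVersion("dmscreen")),
    seed = cfg$seed,
    stage_seeds = list(library = child_seed(cfg$seed, "library"),
                       selection = child_seed(cfg$seed, "selection"),
                       reads_unselected = child_seed(cfg$seed,
                                                     "reads-unselected"),
                       reads_selected = child_seed(cfg$seed,
                                                   "reads-selected"),
                       assays = child_seed(cfg$seed, "assays")),
    gene = preset$gene_id, L = preset$L,
    lambda_mut = preset$lambda_mut, n_clones = cfg$n_clones,
    screen = cfg$screen, sequencing = cfg$sequencing,
    pseudocount = cfg$pseudocount,
    min_reads_per_barcode = cfg$min_reads_per_barcode,
    top_k = cfg$top_k,
    n_selected_cells = n_colonies,
    library_qc = list(mean_mut_per_clone = qc$mean_mut_per_clone,
                      poisson_gof_p = qc$poisson_gof_p,
                      positional_cv = qc$positional_cv))
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(out_dir = cfg$out_dir, preset = preset, library = lib,
                 screen = screen, tables = tables, stats = stats,
                 scores = scores, top_substitutions = top, qc = qc,
                 assays = assays))
}

run_assays <- function(assays, seed, out_dir) {
  out <- list()
  if (!is.null(assays$plating)) {
    a <- assays$plating
    reps <- a$replicates %||% 6L
    wt_rate <- a$true_rate_wt %||% 1e-5
    n_cells <- a$n_cells %||% 1e8
    rows <- lapply(a$variants, function(v) {
      tf <- variant_preset(v)$true_fold
      wt <- vapply(seq_len(reps), function(r)
        acquisition_rate(simulate_plating(wt_rate, n_cells,
          seed = child_seed(seed, paste0("wt-", v, "-", r))))$rate,
        numeric(1))
      var <- vapply(seq_len(reps), function(r)
        acquisition_rate(simulate_plating(tf * wt_rate, n_cells,
          seed = child_seed(seed, paste0(v, "-", r))))$rate,
        numeric(1))
      fc <- fold_change(var, wt)
      data.frame(variant = v, true_fold = tf, fold = fc$fold,
                 t = fc$t, df = fc$df, p = fc$p,
                 stringsAsFactors = FALSE)
    })
    out$plating <- do.call(rbind, rows)
    write_tsv_(out$plating, file.path(out_dir, "assay_plating.tsv"))
  }
  if (!is.null(assays$phage)) {
    a <- assays$phage
    rows <- lapply(a$variants, function(v) {
      rec <- simulate_phage_survival(a$mu_crispr_wt %||% 70,
                                     a$nu_noncrispr %||% 50,
                                     variant = v,
                                     n_colonies_assayed = a$n_assayed %||% 12L,
                                     seed = child_seed(seed, paste0("phage-", v)))
      data.frame(variant = v,
                 true_fold = variant_preset(v)$true_fold,
                 fold = unname(phage_immunity_fold(rec)),
                 stringsAsFactors = FALSE)
    })
    out$phage <- do.call(rbind, rows)
    write_tsv_(out$phage, file.path(out_dir, "assay_phage.tsv"))
  }
  out
}

#' Render a human-readable summary report for a run directory
#'
#' Sections: library QC, differential-selection matrix summary,
#' top-substitution table, assay summary.  Missing artifacts are
#' listed and the remaining sections rendered.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @param path output file (default `report.txt` in the run
#'   directory).
#' @return `path`, invisibly.
#' @export
render_report <- function(run_dir, path = file.path(run_dir, "report.txt")) {
  need <- c(manifest = "manifest.json",
            diffsel = "diffsel_matrix.tsv",
            scores = "site_scores.tsv",
            top = "top_substitutions.tsv")
  have <- setNames(file.exists(file.path(run_dir, need)), names(need))
  lines <- c("DMS screen report", strrep("=", 17), "")
  if (any(!have))
    lines <- c(lines, paste("MISSING ARTIFACTS:",
                            paste(need[!have], collapse = ", ")), "")
  if (have["manifest"]) {
    m <- jsonlite::read_json(file.path(run_dir, "manifest.json"),
                             simplifyVector = TRUE)
    lines <- c(lines, "## Library QC",
               sprintf("gene %s: L=%d codons, lambda=%.2f, %d clones",
                       m$gene, m$L, m$lambda_mut, m$n_clones),
               sprintf("mean mutated codons/clone: %.3f (Poisson GOF p=%.3g)",
                       m$library_qc$mean_mut_per_clone,
                       m$library_qc$poisson_gof_p),
               sprintf("positional CV: %.3f; selected cells: %d",
                       m$library_qc$positional_cv, m$n_selected_cells), "")
  }
  if (have["diffsel"]) {
    d <- read_tsv_(file.path(run_dir, "diffsel_matrix.tsv"))
    aa_cols <- setdiff(names(d), c("site", "wt_aa"))
    lines <- c(lines, "## Differential selection",
               sprintf("matrix: %d sites x %d amino acids (diffsel_matrix.tsv)",
                       nrow(d), length(aa_cols)),
               sprintf("median diffsel: %.3f",
                       median(as.matrix(d[, aa_cols, with = FALSE]))), "")
  }
  if (have["top"]) {
    top <- read_tsv_(file.path(run_dir, "top_substitutions.tsv"))
    lines <- c(lines, "## Top substitutions",
               utils::capture.output(print(as.data.frame(top))), "")
  }
  lines <- c(lines, "## Assays")
  assay_files <- list.files(run_dir, pattern = "^assay_.*\\.tsv$")
  if (length(assay_files) == 0L) {
    lines <- c(lines, "no assay inputs in this run (section absent)", "")
  } else {
    for (f in assay_files)
      lines <- c(lines, paste0("### ", f),
                 utils::capture.output(
                   print(as.data.frame(read_tsv_(file.path(run_dir, f))))),
                 "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `run-all` (full pipeline from a JSON config),
#' `report` (render the report for a run directory),
#' `simulate-library`, `process-reads`, `dms-stats`, `score-sites`.
#' Designed to be called from
#' `Rscript -e 'quit(status = dmscreen::dms_cli())'` or the wrapper in
#' `inst/scripts/dmscreen`.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return Integer exit status: 0 success, 1 usage error, 2 data
#'   error.
#' @export
dms_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dmscreen <subcommand> [options]",
    "  run-all          --config <json> [--out <dir>]",
    "  report           --run <dir>",
    "  simulate-library --config <json> [--out <dir>]",
    "  process-reads    --fastq <file> --reference <fasta> --segments <tsv> --out <tsv>",
    "  dms-stats        --selected <tsv> --unselected <tsv> --reference <fasta> --out <dir>",
    "  score-sites      --stats <dir> --out <tsv> [--k <int>]",
    sep = "\n")
  if (length(args) == 0L) { message(usage); return(1L) }
  cmd <- args[1L]
  opts <- parse_cli_flags(args[-1L])
  res <- tryCatch(switch(cmd,
    "run-all" = {
      cfg <- load_run_config(opts$config %||% stop("--config required"))
      if (!is.null(opts$out)) cfg$out_dir <- opts$out
      run_pipeline(cfg); 0L
    },
    "report" = {
      render_report(opts$run %||% stop("--run required")); 0L
    },
    "simulate-library" = {
      cfg <- load_run_config(opts$config %||% stop("--config required"))
      if (!is.null(opts$out)) cfg$out_dir <- opts$out
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      preset <- resolve_gene(cfg$gene, cfg$n_clones)
      lib <- simulate_clone_library(preset,
                                    seed = child_seed(cfg$seed, "library"))
      write_reference_fasta(preset, file.path(cfg$out_dir, "reference.fasta"))
      write_truth_table(lib, effects_from_config(cfg$effects),
                        file.path(cfg$out_dir, "truth.tsv"))
      0L
    },
    "process-reads" = {
      ref <- read_reference_fasta(opts$reference %||% stop("--reference required"))
      segments <- as.data.frame(read_tsv_(opts$segments %||% stop("--segments required")))
      reads <- read_fastq(opts$fastq %||% stop("--fastq required"))
      cons <- call_consensus(group_by_barcode(reads,
        as.integer(opts$`min-reads` %||% 2L)))
      tab <- count_codons(cons, ref$wt_codons, segments)
      write_codon_counts(tab, opts$out %||% "codon_counts.tsv")
      0L
    },
    "dms-stats" = {
      ref <- read_reference_fasta(opts$reference %||% stop("--reference required"))
      sel <- read_codon_counts(opts$selected %||% stop("--selected required"),
                               ref$wt_codons, "selected")
      unsel <- read_codon_counts(opts$unselected %||% stop("--unselected required"),
                                 ref$wt_codons, "unselected")
      out <- opts$out %||% "."
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      sel_aa <- aggregate_to_aa(to_rpm(sel))
      unsel_aa <- aggregate_to_aa(to_rpm(unsel))
      prefs <- preferences(enrichment(sel_aa, unsel_aa))
      dsel <- differential_selection(sel_aa, unsel_aa)
      write_site_matrix(prefs, file.path(out, "preferences.tsv"))
      write_site_matrix(dsel, file.path(out, "diffsel.tsv"), value = "diffsel")
      write_site_matrix(dsel, file.path(out, "diffsel_matrix.tsv"),
                        layout = "wide")
      0L
    },
    "score-sites" = {
      statsdir <- opts$stats %||% stop("--stats required")
      prefs <- site_matrix_from_tidy(file.path(statsdir, "preferences.tsv"))
      dsel <- site_matrix_from_tidy(file.path(statsdir, "diffsel.tsv"),
                                    wide = file.path(statsdir,
                                                     "diffsel_matrix.tsv"))
      scores <- score_sites(prefs, dsel)
      write_site_scores(scores, dsel, opts$out %||% "site_scores.tsv")
      0L
    },
    { message("unknown subcommand: ", cmd, "\n", usage); 1L }),
    error = function(e) { message("error: ", conditionMessage(e)); 2L })
  res
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i])
    key <- substring(args[i], 3L)
    if (i == length(args)) stop("flag --", key, " needs a value")
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

site_matrix_from_tidy <- function(path, wide = NULL) {
  dt <- read_tsv_(path)
  names(dt)[3L] <- "value"
  m <- as.matrix(data.table::dcast(dt, site ~ aa,
                                   value.var = "value")[, -1L])
  rownames(m) <- seq_len(nrow(m))
  if (!is.null(wide) && file.exists(wide)) {
    w <- read_tsv_(wide)
    if ("wt_aa" %in% names(w)) attr(m, "wt_aa") <- w$wt_aa
  }
  m
}
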