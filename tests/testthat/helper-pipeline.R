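# Shared screen-pipeline runner: simulate -> sequence -> process ->
# dms_core -> site_scoring, at a realistic screen regime (about
# two selected colonies per clone, three unselected molecules per
# clone and segment).
run_screen_pipeline <- function(seed, effects = effect_table(),
                                preset = dms_preset("cas1",
                                                    n_clones = 10000L),
                                n_segments = 3L,
                                base_rate = 1e-4, n_cells = 2e8,
                                unsel_molecules = 3L * preset$n_clones,
                                sel_molecules = NULL) {
  lib <- simulate_clone_library(preset, seed = child_seed(seed, "lib"))
  cfg <- screen_config(base_rate = base_rate, n_cells = n_cells,
                       reads_per_barcode = 2L, seq_error_rate = 1e-3,
                       seed = child_seed(seed, "sel"))
  scr <- simulate_selection(lib, effects, cfg)
  segs <- default_segments(preset$L, n_segments = n_segments)
  if (is.null(sel_molecules)) sel_molecules <- unsel_molecules
  tabs <- list()
  for (sample in c("unselected", "selected")) {
    cfg$seed <- child_seed(seed, paste0("reads-", sample))
    nm <- if (sample == "selected") sel_molecules else unsel_molecules
    reads <- simulate_reads(scr[[sample]], lib, cfg, segs,
                            n_molecules = nm)
    cons <- call_consensus(group_by_barcode(reads, 2L))
    tabs[[sample]] <- count_codons(cons, preset$wt_codons, segs,
                                   sample_id = sample)
  }
  sel_aa <- aggregate_to_aa(to_rpm(tabs$selected))
  unsel_aa <- aggregate_to_aa(to_rpm(tabs$unselected))
  dsel <- differential_selection(sel_aa, unsel_aa)
  prefs <- preferences(enrichment(sel_aa, unsel_aa))
  scores <- score_sites(prefs, dsel)
  list(library = lib, screen = scr, tables = tabs, diffsel = dsel,
       preferences = prefs, scores = scores)
}

# hand-built miniature clone library (bypasses the generator) for
# selection-model unit tests
manual_library <- function(L, n_clones, mutations, gene_id = "toy") {
  preset <- library_preset(gene_id, L = L, lambda_mut = 1,
                           n_clones = n_clones)
  mut <- data.table::as.data.table(mutations)
  data.table::setkey(mut, clone_id, position)
  structure(list(preset = preset, mutations = mut, n_clones = n_clones),
            class = "clone_library")
}
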