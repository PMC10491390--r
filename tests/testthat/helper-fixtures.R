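# Shared in-code fixtures: a small hand-built taxonomy and table builders.

# root order O
#   family F
#     subfamily SF -> genus G (t1, t2), genus H (t3)
#     genus K (t4)          (no subfamily)
#   family F2 -> genus M (t5)
demo_tree <- function() {
  taxonomy_tree(
    taxid  = c("O", "F", "SF", "G", "H", "K", "F2", "M",
               "t1", "t2", "t3", "t4", "t5"),
    name   = c("OrderO", "FamF", "SubSF", "GenG", "GenH", "GenK",
               "FamF2", "GenM", "Sp1", "Sp2", "Sp3", "Sp4", "Sp5"),
    rank   = c("order", "family", "subfamily", "genus", "genus", "genus",
               "family", "genus", rep("species", 5)),
    parent = c("O", "O", "F", "SF", "SF", "F", "O", "F2",
               "G", "G", "H", "K", "M")
  )
}

hit_tbl <- function(taxid, score, model = "m1") {
  data.frame(model_id = rep_len(model, length(taxid)),
             seq_id = sprintf("s%d", seq_along(taxid)),
             taxid = taxid, evalue = rep_len(1e-10, length(taxid)),
             full_score = score, stringsAsFactors = FALSE)
}

stats_tbl <- function(taxon, mean_cds, sd_cds, tsr) {
  data.frame(taxon = taxon, mean_cds = mean_cds, sd_cds = sd_cds,
             tsr = tsr, stringsAsFactors = FALSE)
}

vote_hits <- function(taxon, confidence = "high") {
  n <- length(taxon)
  data.frame(cds_id = sprintf("c_%d", seq_len(n)),
             model_id = sprintf("m%d", seq_len(n)),
             taxon = taxon, rank = rep_len(NA_character_, n),
             confidence = rep_len(confidence, n),
             stringsAsFactors = FALSE)
}

# one (model, cds) domtblout row in genuine fixed-width-ish layout
domtbl_line <- function(model, cds, evalue, full, dom, dom_i = 1, dom_n = 1) {
  sprintf(paste0("%-20s -          120 %-20s -          200 %9.2g %6.1f",
                 "   0.1 %3d %3d %9.2g %9.2g %6.1f   0.1     1   100",
                 "     5   104     1   110 0.95 -"),
          model, cds, evalue, full, dom_i, dom_n, evalue, evalue * 2, dom)
}
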