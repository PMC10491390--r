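ev1 <- function(...) {
  # single-contig evidence table built from named predictor fields
  args <- list(...)
  lens <- c(x = 10000)
  combine_evidence(
    lens,
    virsorter = args$virsorter,
    virfinder = args$virfinder,
    pprmeta = args$pprmeta
  )
}

vs_row <- function(cat, start = NA, end = NA)
  data.frame(contig_id = "x", category = cat, start = start, end = end)
vf_row <- function(score, pvalue)
  data.frame(contig_id = "x", score = score, pvalue = pvalue)
pm_row <- function(class) data.frame(contig_id = "x", class = class)

verdict_of <- function(ev) triage_contigs(ev)$verdict

test_that("triage implements the HC/PP/LC rules and precedence", {
  expect_equal(verdict_of(ev1(virsorter = vs_row(1))), "HC")
  expect_equal(verdict_of(ev1(virsorter = vs_row(2))), "HC")

  asg <- triage_contigs(ev1(virsorter = vs_row(4, 10000, 45000)))
  expect_equal(asg$verdict, "PP")
  expect_equal(asg$regions[[1]]$start, 9999)   # 1-based in, 0-based out
  expect_equal(asg$regions[[1]]$end, 45000)

  expect_equal(verdict_of(ev1(virfinder = vf_row(0.92, 0.01),
                              pprmeta = pm_row("chromosome"))), "LC")
  expect_equal(verdict_of(ev1(virfinder = vf_row(0.75, 0.01),
                              pprmeta = pm_row("phage"))), "LC")
  expect_equal(verdict_of(ev1(virfinder = vf_row(0.75, 0.01),
                              virsorter = vs_row(3))), "LC")
  expect_equal(verdict_of(ev1(virfinder = vf_row(0.75, 0.01))), "excluded")
  expect_equal(verdict_of(ev1()), "excluded")

  # precedence: HC > PP > LC
  expect_equal(verdict_of(ev1(virsorter = vs_row(1),
                              virfinder = vf_row(0.95, 0.001))), "HC")
  expect_equal(verdict_of(ev1(virsorter = vs_row(5, 1, 5000),
                              virfinder = vf_row(0.95, 0.001))), "PP")
})

test_that("boundary semantics: scores inclusive, p-value exclusive", {
  expect_equal(verdict_of(ev1(virfinder = vf_row(0.9, 0.049))), "LC")
  expect_equal(verdict_of(ev1(virfinder = vf_row(0.9, 0.05))), "excluded")
  expect_equal(verdict_of(ev1(virfinder = vf_row(0.7, 0.01),
                              virsorter = vs_row(3))), "LC")
  expect_equal(verdict_of(ev1(virfinder = vf_row(0.699, 0.01),
                              virsorter = vs_row(3))), "excluded")
})

test_that("category 6 is PP-eligible only when toggled on", {
  ev <- ev1(virsorter = vs_row(6, 100, 900))
  expect_equal(triage_contigs(ev)$verdict, "excluded")
  expect_equal(triage_contigs(ev, allow_cat6 = TRUE)$verdict, "PP")
  expect_error(ev1(virsorter = vs_row(7)), "category")
})

test_that("verdicts partition random evidence and only PP carries regions", {
  set.seed(11)
  n <- 60
  lens <- stats::setNames(rep(50000, n), sprintf("c%02d", 1:n))
  vs <- data.frame(contig_id = sample(names(lens), 25),
                   category = sample(1:6, 25, replace = TRUE),
                   start = 100, end = 4000)
  vf <- data.frame(contig_id = sample(names(lens), 40, replace = FALSE),
                   score = runif(40), pvalue = runif(40, 0, 0.2))
  pm <- data.frame(contig_id = names(lens),
                   class = sample(c("phage", "chromosome", "plasmid"), n,
                                  replace = TRUE))
  asg <- triage_contigs(combine_evidence(lens, vs, vf, pm))
  expect_equal(nrow(asg), n)
  expect_equal(anyDuplicated(asg$contig_id), 0L)
  expect_true(all(asg$verdict %in% c("HC", "LC", "PP", "excluded")))
  has_rg <- vapply(asg$regions, function(r) !is.null(r) && nrow(r) > 0,
                   logical(1))
  expect_equal(has_rg, asg$verdict == "PP")
})

test_that("length_filter keeps the boundary and reports counts", {
  sq <- Biostrings::DNAStringSet(c(a = strrep("A", 1499),
                                   b = strrep("C", 1500),
                                   c = strrep("G", 5000)))
  lf <- length_filter(sq)
  expect_equal(names(lf$kept), c("b", "c"))
  expect_equal(lf$report, list(n_in = 3L, n_kept = 2L, n_dropped = 1L))
  expect_equal(names(length_filter(sq, 5000)$kept), "c")   # virome setting
  expect_equal(length_filter(sq, 6000)$report$n_kept, 0L)
})

test_that("extract_regions excises half-open intervals with stable names", {
  s <- Biostrings::DNAStringSet(c(ct = paste(rep(c("A", "C", "G", "T"), 25),
                                             collapse = "")))
  rg <- data.frame(start = 10, end = 20)
  out <- extract_regions(s, rg, contig_id = "ct")
  expect_equal(BiocGenerics::width(out), 10L)
  expect_equal(names(out), "ct|prophage-10:20")
  expect_equal(as.character(out[[1]]),
               as.character(Biostrings::subseq(s[[1]], 11, 20)))
  whole <- extract_regions(s, data.frame(start = 0, end = 100))
  expect_equal(as.character(whole[[1]]), as.character(s[[1]]))
  expect_error(extract_regions(s, data.frame(start = 0, end = 101)),
               "out of range")
})

test_that("run_triage writes the full artifact set from files", {
  dir <- tempfile(); dir.create(dir)
  sq <- Biostrings::DNAStringSet(stats::setNames(
    vapply(1:4, function(i) strrep("ACGT", 1000), character(1)),
    c("h1", "l1", "p1", "e1")))
  fa <- file.path(dir, "in.fa")
  Biostrings::writeXStringSet(sq, fa)
  vs <- file.path(dir, "vs.csv")
  data.table::fwrite(data.frame(contig_id = c("h1", "p1"),
                                category = c(1, 4),
                                start = c(NA, 101), end = c(NA, 1100)), vs)
  vf <- file.path(dir, "vf.tsv")
  data.table::fwrite(data.frame(name = "l1", length = 4000, score = 0.95,
                                pvalue = 0.001), vf, sep = "\t")
  out <- file.path(dir, "out")
  asg <- run_triage(fa, virsorter = vs, virfinder = vf, out_dir = out)
  expect_equal(asg[asg$contig_id == "h1", ]$verdict, "HC")
  expect_equal(asg[asg$contig_id == "l1", ]$verdict, "LC")
  expect_equal(asg[asg$contig_id == "p1", ]$verdict, "PP")
  expect_equal(asg[asg$contig_id == "e1", ]$verdict, "excluded")
  expect_true(file.exists(file.path(out, "hc_lc_contigs.fasta")))
  pp <- Biostrings::readDNAStringSet(file.path(out, "prophage_regions.fasta"))
  expect_equal(names(pp), "p1|prophage-100:1100")
  expect_equal(BiocGenerics::width(pp), 1000L)
  expect_true(file.exists(file.path(out, "prophage_regions.bed")))
  expect_true(file.exists(file.path(out, "triage_assignments.tsv")))
})
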