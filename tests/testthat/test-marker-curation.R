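test_that("best_scores_by_taxon keeps per-taxid maxima and groups by rank", {
  tree <- demo_tree()
  rg <- best_scores_by_taxon(hit_tbl(c("t1", "t1", "t2"), c(60, 42, 55)),
                             tree, "genus")
  expect_equal(rg$taxon, "G")
  expect_equal(rg$low, 55)
  expect_equal(rg$high, 60)

  rg1 <- best_scores_by_taxon(hit_tbl("t1", 60), tree, "genus")
  expect_equal(c(rg1$low, rg1$high), c(60, 60))

  # order-level node has no genus ancestor -> dropped
  expect_equal(nrow(best_scores_by_taxon(hit_tbl("O", 50), tree, "genus")),
               0L)
  expect_equal(nrow(best_scores_by_taxon(hit_tbl(character(0), numeric(0)),
                                         tree, "genus")), 0L)
})

test_that("select_informative applies both conditions with escalation", {
  tree <- demo_tree()
  # G range [55,60] vs H [40,40]: separated at genus
  sel <- select_informative(
    hit_tbl(c("t1", "t2", "t3"), c(60, 55, 40)), tree)
  expect_equal(sel[c("rank", "taxon", "S1", "S2")],
               list(rank = "genus", taxon = "G", S1 = 55, S2 = 40))

  # G [55,60] vs H [58,58] overlap; both under SF -> single subfamily taxon
  sel2 <- select_informative(
    hit_tbl(c("t1", "t2", "t3"), c(60, 55, 58)), tree)
  expect_equal(sel2$rank, "subfamily")
  expect_equal(sel2$taxon, "SF")
  expect_equal(sel2$S1, 55)
  expect_true(is.na(sel2$S2))

  # single taxid
  sel3 <- select_informative(hit_tbl("t1", 60), tree)
  expect_equal(sel3[c("rank", "taxon", "S1")],
               list(rank = "genus", taxon = "G", S1 = 60))
  expect_true(is.na(sel3$S2))

  # exact boundary: best low == other high -> not separated (strict >)
  sel4 <- select_informative(hit_tbl(c("t1", "t3"), c(58, 58)), tree)
  expect_false(identical(sel4$rank, "genus"))

  expect_null(select_informative(hit_tbl(character(0), numeric(0)), tree))
})

test_that("select_informative agrees with the exhaustive oracle", {
  spec <- fixture_spec(seed = 42, n_orders = 2, n_families = 3,
                       n_subfamilies = 2, n_genera = 5, taxids_per_genus = 2)
  tree <- make_taxonomy(spec)
  leaves <- tree$taxid[tree$rank == "species"]
  set.seed(99)
  for (i in 1:150) {
    k <- sample(1:6, 1)
    h <- hit_tbl(sample(leaves, k, replace = TRUE),
                 round(runif(k, 20, 80), 1))
    got <- select_informative(h, tree)
    exp <- oracle_select_informative(h, tree)
    if (is.null(exp)) {
      expect_null(got)
    } else {
      expect_equal(got[c("rank", "taxon", "S1")],
                   exp[c("rank", "taxon", "S1")])
      expect_equal(is.na(got$S2), is.na(exp$S2))
      if (!is.na(exp$S2)) expect_equal(got$S2, exp$S2)
    }
  }
})

test_that("informativeness is invariant to duplicates and hit order", {
  tree <- demo_tree()
  h <- hit_tbl(c("t1", "t2", "t3", "t4"), c(60, 55, 40, 30))
  base <- select_informative(h, tree)
  expect_equal(select_informative(h[c(4, 2, 1, 3), ], tree), base)
  expect_equal(select_informative(rbind(h, h), tree), base)
})

test_that("derive_thresholds implements the trim guard", {
  expect_equal(derive_thresholds(50, 40),
               list(GA_seq = 50, GA_dom = 47, TC_seq = 50, TC_dom = 47,
                    NC_seq = 40, NC_dom = 40))
  th <- derive_thresholds(50, 48.5)             # S1 - 3 <= S2: no trim
  expect_equal(th$GA_dom, 50)
  expect_equal(th$NC_seq, 48.5)
  th2 <- derive_thresholds(50)                  # S2 absent: trim applies
  expect_equal(th2$GA_dom, 47)
  expect_equal(th2$GA_seq, 50)
  expect_true(is.na(th2$NC_seq))
  expect_error(derive_thresholds(50, 50), "calibration error")
  expect_error(derive_thresholds(50, 51), "calibration error")
})

test_that("threshold ordering NC < TC_dom <= TC_seq holds whenever S2 exists", {
  set.seed(7)
  for (i in 1:50) {
    S1 <- runif(1, 20, 90)
    S2 <- S1 - runif(1, 0.1, 20)
    th <- derive_thresholds(S1, S2)
    expect_lt(th$NC_dom, th$TC_dom)
    expect_lte(th$TC_dom, th$TC_seq)
    expect_equal(th$GA_seq, th$TC_seq)
    expect_equal(th$GA_dom, th$TC_dom)
  }
})

test_that("annotate_hmm writes, replaces and round-trips cutoff lines", {
  marker <- list(GA_seq = 50, GA_dom = 47, TC_seq = 50, TC_dom = 47,
                 NC_seq = 40, NC_dom = 40)
  txt <- synthetic_hmm_text("VMRK00001")
  out <- annotate_hmm(txt, marker)
  expect_true("GA    50.00 47.00;" %in% out)
  expect_true("TC    50.00 47.00;" %in% out)
  expect_true("NC    40.00 40.00;" %in% out)
  # cutoffs sit right after CKSUM
  expect_equal(grep("^GA", out), grep("^CKSUM", out) + 1L)
  # body untouched byte-for-byte
  hmm_at_in <- grep("^HMM\\s", txt)
  hmm_at_out <- grep("^HMM\\s", out)
  expect_identical(out[hmm_at_out:length(out)], txt[hmm_at_in:length(txt)])
  # idempotent
  expect_identical(annotate_hmm(out, marker), out)
  # re-parse yields the marker's thresholds
  expect_equal(read_hmm_cutoffs(out),
               list(GA_seq = 50, GA_dom = 47, TC_seq = 50, TC_dom = 47,
                    NC_seq = 40, NC_dom = 40))
  # no NC line when absent
  m2 <- list(GA_seq = 50, GA_dom = 47, TC_seq = 50, TC_dom = 47,
             NC_seq = NA_real_, NC_dom = NA_real_)
  out2 <- annotate_hmm(txt, m2)
  expect_length(grep("^NC", out2), 0L)
  expect_error(annotate_hmm(c("not a model"), marker), "HMMER3")
})

test_that("curate_markers applies the reporting E-value filter", {
  tree <- demo_tree()
  h <- hit_tbl(c("t1", "t2", "t3"), c(60, 55, 40))
  h$evalue <- c(1e-10, 1e-10, 0.5)   # t3 fails the e-value gate
  mk <- curate_markers(h, tree)
  expect_equal(mk$taxon, "G")
  expect_true(is.na(mk$S2))          # competitor filtered out
})
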