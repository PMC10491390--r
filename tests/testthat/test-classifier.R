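test_that("parse_domain_table extracts fields and collapses domains", {
  f <- tempfile()
  writeLines(c("# comment",
               domtbl_line("mA", "c1_1", 1e-10, 52.0, 30.0, 1, 2),
               domtbl_line("mA", "c1_1", 1e-10, 52.0, 45.0, 2, 2),
               domtbl_line("mB", "c1_2", 2e-5, 33.5, 31.0)), f)
  h <- parse_domain_table(f)
  expect_equal(nrow(h), 2L)
  a <- h[h$model_id == "mA", ]
  expect_equal(a$dom_score, 45)                 # best of 30/45
  expect_equal(a$full_score, 52)
  b <- h[h$model_id == "mB", ]
  expect_equal(b$cds_id, "c1_2")
  expect_equal(b$full_evalue, 2e-5)
  expect_equal(b$dom_score, 31)

  f2 <- tempfile(); writeLines(c("# only", "# comments"), f2)
  expect_equal(nrow(parse_domain_table(f2)), 0L)

  f3 <- tempfile(); writeLines(c("# ok", "too few fields"), f3)
  expect_error(parse_domain_table(f3), "line 2")
})

test_that("gate_hits applies GA gating and the E-value fallback", {
  mk <- data.frame(model_id = c("mA", "mU"), taxon = c("G", "H"),
                   rank = "genus",
                   GA_seq = c(50, NA), GA_dom = c(47, NA))
  hits <- data.frame(
    model_id = c("mA", "mA", "mA", "mU", "mU", "mZ"),
    cds_id = paste0("c1_", 1:6),
    full_evalue = c(1e-9, 1e-9, 1e-9, 5e-4, 0.01, 1e-9),
    full_score = c(52, 52, 49, 20, 20, 80),
    dom_score = c(48, 46, 48, 18, 18, 79))
  g <- gate_hits(hits, mk)
  expect_equal(sort(g$cds_id), c("c1_1", "c1_4"))
  expect_equal(g[g$cds_id == "c1_1", ]$confidence, "high")
  expect_equal(g[g$cds_id == "c1_4", ]$confidence, "low")
  # an extra known-but-uncalibrated model id keeps its hits (no taxon)
  g2 <- gate_hits(hits, mk, all_models = "mZ")
  expect_true("c1_6" %in% g2$cds_id)
  expect_true(is.na(g2[g2$cds_id == "c1_6", ]$taxon))
})

test_that("best_hit_per_cds dedups with the documented tie-breaks", {
  h <- data.frame(
    model_id = c("m1", "m2", "mA", "mB", "solo"),
    cds_id = c("k_1", "k_1", "k_2", "k_2", "k_3"),
    full_evalue = 1e-9,
    full_score = c(40, 55, 55, 55, 10),
    dom_score = c(39, 54, 30, 40, 9),
    taxon = "G", rank = "genus", confidence = "high")
  d <- best_hit_per_cds(h)
  expect_equal(d[d$cds_id == "k_1", ]$model_id, "m2")   # higher full score
  expect_equal(d[d$cds_id == "k_2", ]$model_id, "mB")   # domain tie-break
  expect_equal(d[d$cds_id == "k_3", ]$model_id, "solo")
  expect_equal(unique(d$contig_id), "k")

  h$cds_id <- c("k_1", "k_1", "k_2", "k_2", "orphan")
  d2 <- best_hit_per_cds(h)
  expect_equal(attr(d2, "orphans"), "orphan")
  expect_false("orphan" %in% d2$cds_id)
})

test_that("vote reproduces the worked genus and escalation cases", {
  tree <- demo_tree()
  st <- stats_tbl(c("G", "H", "SF"),
                  mean_cds = c(12, 12, 25), sd_cds = c(2, 2, 5),
                  tsr = c(0.8, 0.8, 1))
  hits <- vote_hits(c(rep("G", 5), "H"))

  v <- vote(hits, n_cds = 10, st, tree)
  expect_equal(v$outcome, "classified")
  expect_equal(v$deciding_rank, "genus")
  expect_equal(v$taxon, "G")
  expect_equal(v$proportion, 5 / 6)
  expect_equal(unname(v$lineage["subfamily"]), "SF")
  expect_equal(unname(v$lineage["order"]), "O")

  # n_cds 20: G fails CDS bound (20 > 16), H fails proportion;
  # escalates to subfamily SF where proportion 1 >= 0.6 and 20 <= 35
  v2 <- vote(hits, n_cds = 20, st, tree)
  expect_equal(v2$deciding_rank, "subfamily")
  expect_equal(v2$taxon, "SF")
  expect_equal(v2$proportion, 1)

  expect_equal(vote(vote_hits(character(0)), 10, st, tree)$outcome,
               "unclassified")

  # factor 0 with permissive stats accepts the top genus immediately
  v0 <- vote(hits, n_cds = 10, st, tree, factor = 0)
  expect_equal(v0$deciding_rank, "genus")
  expect_equal(v0$taxon, "G")
})

test_that("candidates without statistics get TSR 1 and a waived CDS bound", {
  tree <- demo_tree()
  hits <- vote_hits(rep("G", 4))
  expect_warning(v <- vote(hits, 1000, stats_tbl(character(0), numeric(0),
                                                 numeric(0), numeric(0)),
                           tree),
                 "TSR set to 1")
  expect_equal(v$outcome, "classified")   # proportion 1 >= 0.6 * 1, waived
  expect_equal(v$taxon, "G")
})

test_that("hits vote through lineage ascent and coarse markers stay in the denominator", {
  tree <- demo_tree()
  st <- stats_tbl(c("G", "F"), c(20, 30), c(2, 5), c(0.5, 0.9))
  # an order-level marker cannot vote at genus but dilutes the proportion
  hits <- vote_hits(c("G", "G", "O"))
  v <- vote(hits, 10, st, tree)
  expect_equal(v$proportion, 2 / 3)
  expect_equal(v$taxon, "G")
  # at family rank a genus marker supports its family; SF is made to fail
  # the CDS bound so the vote escalates past subfamily
  hits2 <- vote_hits(c("G", "H", "K"))   # all under F; no genus majority
  st2 <- stats_tbl(c("G", "H", "K", "SF", "F"),
                   c(20, 20, 20, 5, 20), c(1, 1, 1, 0, 1),
                   c(1, 1, 1, 1, 0.9))
  v2 <- vote(hits2, 10, st2, tree)
  expect_equal(v2$deciding_rank, "family")
  expect_equal(v2$taxon, "F")
  expect_equal(v2$proportion, 1)
})

test_that("count_cds works for GFF3 and protein FASTA conventions", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tCDS\t1\t300\t.\t+\t0\tID=c1_1",
               "c1\tsrc\tCDS\t400\t900\t.\t+\t0\tID=c1_2",
               "c2\tsrc\tCDS\t1\t200\t.\t-\t0\tID=c2_1"), gff)
  cc <- count_cds(gff, "gff3")
  expect_equal(cc[["c1"]], 2L)
  expect_equal(cc[["c2"]], 1L)

  faa <- tempfile(fileext = ".faa")
  writeLines(c(">c1_1 desc", "MK", ">c1_2", "MA", ">c2_1", "MV"), faa)
  expect_equal(count_cds(faa, "faa"), c(c1 = 2L, c2 = 1L))
})

test_that("classify_contigs ties the pieces together and exports Krona text", {
  tree <- demo_tree()
  mk <- data.frame(model_id = c("mG", "mH"), taxon = c("G", "H"),
                   rank = "genus", GA_seq = c(50, 50), GA_dom = c(47, 47))
  st <- stats_tbl(c("G", "H"), c(10, 10), c(1, 1), c(0.6, 0.6))
  f <- tempfile()
  writeLines(c(domtbl_line("mG", "ctg_1", 1e-12, 60, 58),
               domtbl_line("mG", "ctg_2", 1e-12, 55, 53),
               domtbl_line("mH", "ctg_3", 1e-12, 52, 50)), f)
  cl <- classify_contigs(f, mk, st, tree, cds_counts = c(ctg = 8L))
  expect_equal(cl$outcome, "classified")
  expect_equal(cl$taxon, "G")
  expect_equal(cl$n_hits_high, 3L)
  expect_equal(cl$lineage, "OrderO;FamF;SubSF;GenG")
  kr <- krona_text(cl, tree)
  expect_equal(kr, "1\tOrderO\tFamF\tSubSF\tGenG")
})
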