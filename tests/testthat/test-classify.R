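# A controlled library: one family, two genera, with enough sequence
# structure that mates of a read pair hit their own species near-perfectly
# and congeners ~8% away.
classify_fixture <- function(seed = 71) {
  withr::with_seed(seed, {
    lib <- generate_reference_library(3, 2, 2, seed = seed)
    ref <- build_ref_index(lib)
    list(lib = lib, ref = ref)
  })
}

mates_of <- function(amplicon, read_len = 250) {
  list(fwd = substr(amplicon, 1, read_len),
       rev = revcomp(substr(amplicon, nchar(amplicon) - read_len + 1,
                            nchar(amplicon))))
}

test_that("dual-read assignment: exact pair hits its species with one hit", {
  fx <- classify_fixture()
  rec <- fx$lib[5, ]
  m <- mates_of(rec$sequence)
  got <- dual_read_assign(m$fwd, m$rev, fx$ref)
  expect_equal(got$mode, "dual_read")
  expect_equal(format_lineage(got$lineage), rec$taxonomy)
  expect_equal(got$best_avg_identity_pct, 100)
  expect_equal(got$n_retained_hits, 1)
})

test_that("consensus walk follows the >= 50% rule with the tie rule", {
  lin <- function(g, s) c("Animalia", "Arthropoda", "Insecta", "Lepidoptera",
                          "Fam", "Subfam", g, s)
  # 2x sp1 + 1x sp2 in one genus: sp1 holds 2/3 >= 0.5 -> species level
  l3 <- list(lin("Gen1", "sp1"), lin("Gen1", "sp1"), lin("Gen1", "sp2"))
  got <- motubar:::consensus_lineage(l3, 0.5)
  expect_equal(got[[8]], "sp1")
  # 2 + 2 split across genera: exact ties at species and genus -> family
  l4 <- list(lin("Gen1", "sp1"), lin("Gen1", "sp1"),
             lin("Gen2", "sp3"), lin("Gen2", "sp3"))
  got4 <- motubar:::consensus_lineage(l4, 0.5)
  expect_length(got4, 6) # down to subfamily, shared by all four
  expect_equal(got4[[5]], "Fam")
  # raising the fraction never deepens the assignment
  depths <- vapply(seq(0.5, 1, by = 0.1), function(f)
    length(motubar:::consensus_lineage(l3, f)), numeric(1))
  expect_true(all(diff(depths) <= 0))
})

test_that("identity window retains near-best hits only", {
  fx <- classify_fixture()
  rec <- fx$lib[1, ]
  m <- mates_of(rec$sequence)
  got <- dual_read_assign(m$fwd, m$rev, fx$ref,
                          classifier_params(identity_window = 0.5))
  # window property: every retained hit within 0.5 of the best average
  expect_true(all(got$hit_avg_identities >=
                    got$best_avg_identity_pct - 0.5))
  # congeners sit ~8% away, so a singleton hit set here
  expect_equal(got$n_retained_hits, 1)
  # a wide window pulls in the congener and shallows the call
  wide <- dual_read_assign(m$fwd, m$rev, fx$ref,
                           classifier_params(identity_window = 15,
                                             consensus_fraction = 0.9))
  expect_gt(wide$n_retained_hits, 1)
  expect_lt(length(wide$lineage), 8)
})

test_that("single-read fallback engages when only one mate matches", {
  fx <- classify_fixture()
  rec <- fx$lib[3, ]
  m <- mates_of(rec$sequence)
  got <- dual_read_assign(m$fwd, NA, fx$ref)
  expect_equal(got$mode, "single_read")
  expect_equal(format_lineage(got$lineage), rec$taxonomy)
  # a reverse mate of pure noise also forces single-read mode
  got2 <- dual_read_assign(m$fwd, withr::with_seed(5, random_seq(250)), fx$ref)
  expect_equal(got2$mode, "single_read")
  # nothing matches anywhere -> unassigned
  noise <- withr::with_seed(6, random_seq(250))
  got3 <- dual_read_assign(noise, revcomp(noise), fx$ref)
  expect_equal(got3$mode, "unassigned")
  expect_length(got3$lineage, 0)
})

test_that("LCA fallback assigns the common prefix of retained hits", {
  fb <- tiny_fallback()
  ref <- build_ref_index(fb)
  ric <- fb$sequence[fb$record_id == "SYM_RICKETTSIA"]
  m <- mates_of(ric)
  got <- lca_assign(m$fwd, m$rev, ref)
  expect_equal(got$mode, "lca_fallback")
  expect_equal(got$lineage[[7]], "Rickettsia")
  # two congeneric-but-distinct genera in one family -> family level
  base <- withr::with_seed(9, random_seq(658))
  twin <- withr::with_seed(10, mutate_random(base, 20))
  recs <- data.frame(
    record_id = c("g1", "g2"),
    taxonomy = c("Bacteria;Proteobacteria;Alpha;Rickettsiales;FamX;TrX;GenA;A_sp",
                 "Bacteria;Proteobacteria;Alpha;Rickettsiales;FamX;TrX;GenB;B_sp"),
    sequence = c(base, twin), stringsAsFactors = FALSE)
  got2 <- lca_assign(substr(base, 1, 250),
                     revcomp(substr(base, 409, 658)),
                     build_ref_index(recs))
  expect_equal(as.character(got2$lineage),
               c("Bacteria", "Proteobacteria", "Alpha", "Rickettsiales",
                 "FamX", "TrX"))
  # LCA soundness: assigned lineage is a prefix of every retained hit
  for (h in got2$hit_ids)
    expect_true(is_lineage_prefix(got2$lineage,
                                  build_ref_index(recs)$lineages[[h]]))
  # no hits -> unassigned
  noise <- withr::with_seed(11, random_seq(250))
  expect_equal(lca_assign(noise, NA, ref)$mode, "unassigned")
})

test_that("categorize_motu applies the ordered default rules", {
  mk <- function(lin, mode = "dual_read")
    motubar:::assignment_result(lineage(lin), mode, 99, "x", 99)
  expect_equal(categorize_motu(mk(c("Animalia", "Arthropoda", "Insecta",
                                    "Lepidoptera", "Geometridae"))), "host")
  expect_equal(categorize_motu(mk(c("Animalia", "Arthropoda", "Insecta",
                                    "Hymenoptera"))), "parasitoid")
  expect_equal(categorize_motu(mk(c("Bacteria", "Proteobacteria"),
                                  "lca_fallback")), "putative_symbiont")
  expect_equal(categorize_motu(mk(c("Plantae", "Tracheophyta"))), "contaminant")
  expect_equal(categorize_motu(mk(c("Animalia", "Arthropoda", "Insecta",
                                    "Coleoptera"))), "contaminant")
  expect_equal(categorize_motu(motubar:::assignment_result(lineage(),
                                                           "unassigned")),
               "unassigned")
})

test_that("standard barcoding identifies within 3% divergence, else shared rank", {
  fx <- classify_fixture()
  rec <- fx$lib[7, ]
  got <- standard_barcode_identify(rec$sequence, fx$ref)
  expect_equal(format_lineage(got$lineage), rec$taxonomy)
  # 2.9% divergence still species
  withr::with_seed(81, {
    near <- mutate_random(rec$sequence, 19) # 19/658 = 2.9%
    got2 <- standard_barcode_identify(near, fx$ref)
    expect_equal(format_lineage(got2$lineage), rec$taxonomy)
    # ~5% divergence: no species call, falls back to a shared (shallower) rank
    far <- mutate_random(rec$sequence, 33)
    got3 <- standard_barcode_identify(far, fx$ref)
    expect_lt(length(got3$lineage), 8)
  })
  expect_warning(standard_barcode_identify(substr(rec$sequence, 1, 300),
                                           fx$ref), "500")
})

test_that("dual-read beats single-read on congeneric confounders", {
  # reduced benchmark (n = 40); the 200-query version runs in acceptance
  fx <- classify_fixture(72)
  acc <- dual_single_benchmark(fx, n_queries = 40, seed = 73)
  expect_gte(acc$dual, acc$single)
})
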