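test_that("reference library: minimal case and determinism", {
  one <- generate_reference_library(1, 1, 1, seed = 1)
  expect_equal(nrow(one), 1)
  expect_length(parse_lineage(one$taxonomy), 8) # complete to species
  expect_equal(nchar(one$sequence), 658)

  again <- generate_reference_library(1, 1, 1, seed = 1)
  expect_identical(one, again)
  other <- generate_reference_library(1, 1, 1, seed = 2)
  expect_false(identical(one$sequence, other$sequence))
})

test_that("library divergence strata are ordered as designed", {
  lib <- generate_reference_library(2, 2, 2, seed = 1)
  expect_equal(nrow(lib), 8)
  lin <- lapply(lib$taxonomy, parse_lineage)
  genus <- vapply(lin, `[`, character(1), 7)
  family <- vapply(lin, `[`, character(1), 5)
  within_genus <- c(); cross_genus <- c(); cross_family <- c()
  for (i in 1:7) for (j in (i + 1):8) {
    al <- align_identity(lib$sequence[i], lib$sequence[j])
    # identity is only meaningful over a substantial overlap: unrelated
    # pairs can score ~100% on chance short overlaps (hence the pipeline's
    # coverage guard); divergence strata are asserted on covered identity
    id <- if (al$aligned_cols >= 100) al$identity_pct else 0
    if (genus[i] == genus[j]) within_genus <- c(within_genus, id)
    else if (family[i] == family[j]) cross_genus <- c(cross_genus, id)
    else cross_family <- c(cross_family, id)
  }
  # congeneric 5-12% divergence, cross-genus/cross-family > 12%
  expect_true(all(within_genus >= 88 & within_genus <= 95))
  expect_true(all(cross_genus < 88))
  expect_true(min(within_genus) >= max(cross_genus))
  expect_true(all(cross_family < 88))
})

test_that("conspecific replicates diverge by less than 1%", {
  lib <- generate_reference_library(1, 1, 2, seed = 9,
                                    replicates_per_species = 1)
  expect_equal(nrow(lib), 4)
  sp <- split(lib$sequence, lib$taxonomy)
  for (s in sp) expect_gte(seq_identity(s[1], s[2]), 99)
})

test_that("unsatisfiable divergence strata error out", {
  expect_error(generate_reference_library(1, 8, 8, seed = 1),
               "unsatisfiable")
  expect_error(generate_reference_library(0, 1, 1, seed = 1))
})

test_that("mock design invariants hold and are validated", {
  d <- tiny_design()
  expect_s3_class(d, "mock_design")
  expect_equal(nrow(d$samples), 5)
  # 5 hosts + 17 parasitoids + 5 symbionts + 5 contaminants
  expect_equal(sum(d$specimens$role == "host"), 5)
  expect_equal(sum(d$specimens$role == "parasitoid"), 17)
  expect_equal(length(unique(d$specimens$taxon_id[
    d$specimens$role %in% c("host", "parasitoid")])), 14)
  sums <- tapply(d$specimens$relative_abundance, d$specimens$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  mids <- d$samples$mid
  for (i in 1:4) for (j in (i + 1):5)
    expect_gte(sum(strsplit(mids[i], "")[[1]] != strsplit(mids[j], "")[[1]]), 3)
  # barcodes stay conspecific with their reference taxon
  lib <- rbind(tiny_library()[c("record_id", "sequence")],
               tiny_fallback()[c("record_id", "sequence")])
  for (i in seq_len(nrow(d$specimens))) {
    ref_seq <- lib$sequence[lib$record_id == d$specimens$taxon_id[i]]
    expect_gte(seq_identity(d$barcodes[[d$specimens$specimen_id[i]]], ref_seq),
               99)
  }
  bad <- d
  bad$specimens$relative_abundance[1] <- 0.9
  expect_error(validate_mock_design(bad), "sum to 1")
})

test_that("error-free reads are exact substrings of their amplicons", {
  d <- tiny_design()
  sim <- simulate_paired_reads(d, reads_per_sample = 50, error_rate = 0,
                               chimera_rate = 0, seed = 5)
  expect_equal(nrow(sim$fwd), 250) # conservation
  expect_setequal(sim$fwd$read_id, sim$manifest$read_id)
  expect_false(any(duplicated(sim$manifest$read_id)))
  mid_of <- setNames(d$samples$mid, d$samples$sample_id)
  for (i in seq_len(50)) {
    mrow <- sim$manifest[i, ]
    amp <- d$barcodes[[mrow$specimen_id]]
    fwd <- sim$fwd$bases[i]
    expect_equal(substr(fwd, 1, 7), unname(mid_of[mrow$sample_id]))
    expect_equal(substr(fwd, 8, 300), substr(amp, 1, 293))
    expect_equal(revcomp(sim$rev$bases[i]),
                 substr(amp, nchar(amp) - 299, nchar(amp)))
  }
})

test_that("chimera and abundance rates follow their distributions", {
  d <- tiny_design()
  sim <- simulate_paired_reads(d, reads_per_sample = 1000, error_rate = 0,
                               chimera_rate = 0.05, seed = 6)
  n_chim <- sum(sim$manifest$is_chimera)
  # binomial CI around 5% of 5000
  expect_gt(n_chim, 250 - 3 * sqrt(5000 * 0.05 * 0.95))
  expect_lt(n_chim, 250 + 3 * sqrt(5000 * 0.05 * 0.95))
  expect_true(all(!is.na(sim$manifest$parent_a[sim$manifest$is_chimera])))
  expect_true(all(is.na(sim$manifest$specimen_id[sim$manifest$is_chimera])))

  # host multinomial expectation: 0.8 of 4000 in one sample
  sim2 <- simulate_paired_reads(d, reads_per_sample = 4000, error_rate = 0,
                                chimera_rate = 0, seed = 7)
  host_sp <- d$specimens$specimen_id[d$specimens$role == "host" &
                                       d$specimens$sample_id == "S1"]
  n_host <- sum(sim2$manifest$specimen_id == host_sp &
                  sim2$manifest$sample_id == "S1")
  se <- sqrt(4000 * 0.8 * 0.2)
  expect_gt(n_host, 3200 - 3 * se)
  expect_lt(n_host, 3200 + 3 * se)
})

test_that("per-specimen read fractions converge to design fractions", {
  d <- tiny_design()
  sim <- simulate_paired_reads(d, reads_per_sample = 10000, error_rate = 0,
                               chimera_rate = 0, seed = 8)
  m1 <- sim$manifest[sim$manifest$sample_id == "S3", ]
  sp <- d$specimens[d$specimens$sample_id == "S3", ]
  for (i in seq_len(nrow(sp))) {
    frac <- mean(m1$specimen_id == sp$specimen_id[i])
    p <- sp$relative_abundance[i]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(frac - p), 3 * se + 1e-12)
  }
})

test_that("simulation is seed-deterministic and rejects bad input", {
  d <- tiny_design()
  a <- simulate_paired_reads(d, reads_per_sample = 20, error_rate = 0.01,
                             chimera_rate = 0.1, seed = 9)
  b <- simulate_paired_reads(d, reads_per_sample = 20, error_rate = 0.01,
                             chimera_rate = 0.1, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_paired_reads(d, reads_per_sample = 0, seed = 1))
  expect_error(simulate_paired_reads(d, reads_per_sample = 10, read_len = 400,
                                     seed = 1), "non-overlapping")
})

test_that("quality strings decay from ~Q38 toward ~Q20", {
  d <- tiny_design()
  sim <- simulate_paired_reads(d, reads_per_sample = 200, error_rate = 0,
                               chimera_rate = 0, seed = 10)
  q <- do.call(rbind, lapply(sim$fwd$quals, function(s) utf8ToInt(s) - 33L))
  means <- colMeans(q)
  expect_gt(means[1], 35)
  expect_lt(means[300], 23)
  expect_lt(means[300], means[1])
})

test_that("fixture tables load with the published shapes and values", {
  t1 <- load_fixture_tables("table1")
  expect_equal(nrow(t1), 9)
  expect_equal(t1$success_pct[t1$method == "morphological" &
                                t1$level == "family"], 100.0)
  expect_true(all(t1$n_individuals == 22))
  # reconstructed counts must be consistent with the printed percentages
  expect_true(all(round(100 * t1$n_success / 22, 1) == t1$success_pct))

  t2 <- load_fixture_tables("table2")
  expect_equal(sum(t2$guild == "parasitoid"), 24)
  expect_equal(sum(t2$guild == "host"), 19)
  expect_equal(t2$n_bins[t2$taxon_group == "Exoristinae"], 12)
  expect_error(load_fixture_tables("table3"))
})
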