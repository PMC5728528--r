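test_that("dereplicate groups, orders, and breaks ties deterministically", {
  got <- dereplicate(c("AAA", "CCC", "AAA", "AAA"), c("r1", "r2", "r3", "r4"))
  expect_equal(got$sequence, c("AAA", "CCC"))
  expect_equal(got$abundance, c(3L, 1L))
  expect_equal(got$read_ids[[1]], c("r1", "r3", "r4"))

  all_diff <- dereplicate(c("TT", "GG", "AA"))
  expect_equal(nrow(all_diff), 3)
  expect_equal(all_diff$abundance, rep(1L, 3))
  expect_equal(all_diff$sequence, c("AA", "GG", "TT")) # lexicographic ties
})

test_that("greedy clustering matches forced cases and the components oracle", {
  withr::with_seed(51, {
    a <- random_seq(200)
    u <- dereplicate(c(a, a))
    got <- greedy_cluster(u)
    expect_equal(nrow(got$motus), 1)
    expect_equal(got$motus$total, 2L)

    b <- mutate_random(a, 20) # 90% identity
    got2 <- greedy_cluster(dereplicate(c(a, b)))
    expect_equal(nrow(got2$motus), 2)

    # 20 reads from 3 species: within < 1%, between >= 5%
    sp <- c(random_seq(300))
    sp[2] <- mutate_random(sp[1], 30)
    sp[3] <- mutate_random(sp[2], 35)
    reads <- character()
    for (i in 1:20) reads <- c(reads,
                               mutate_random(sp[(i %% 3) + 1], sample.int(2, 1)))
    u3 <- dereplicate(reads)
    got3 <- greedy_cluster(u3, threshold_pct = 97)
    expect_equal(nrow(got3$motus), 3)
    expect_equal(nrow(got3$motus), identity_components(u3$sequence, 97))
  })
})

test_that("clustering invariants: separation, membership, monotonicity", {
  withr::with_seed(52, {
    base <- random_seq(250)
    variants <- c(vapply(1:6, function(i) mutate_random(base, 2), character(1)),
                  vapply(1:6, function(i) mutate_random(base, 60), character(1)),
                  vapply(1:4, function(i) random_seq(250), character(1)))
    reads <- sample(rep(variants, times = sample(1:5, 16, replace = TRUE)))
    u <- dereplicate(reads)
    for (thr in c(100, 97, 90)) {
      cl <- greedy_cluster(u, threshold_pct = thr)
      seqs <- cl$motus$centroid_fwd
      # centroid separation (with the coverage guard active)
      if (length(seqs) > 1)
        for (i in 1:(length(seqs) - 1)) for (j in (i + 1):length(seqs)) {
          al <- align_identity(seqs[i], seqs[j])
          expect_true(al$identity_pct < thr ||
                        al$aligned_cols < min(100, nchar(seqs[i]),
                                              nchar(seqs[j])))
        }
      # membership: every member's sequence within threshold of its centroid
      seq_of_read <- setNames(rep(u$sequence, lengths(u$read_ids)),
                              unlist(u$read_ids))
      for (ci in seq_along(cl$members)) {
        for (rid in cl$members[[ci]])
          expect_gte(seq_identity(seq_of_read[[rid]], seqs[ci]), thr)
      }
    }
    counts <- vapply(c(100, 97, 90), function(thr)
      nrow(greedy_cluster(u, threshold_pct = thr)$motus), numeric(1))
    expect_true(all(diff(counts) <= 0)) # non-increasing as threshold drops
  })
})

test_that("singleton removal: per-sample zeroing and total mode", {
  counts <- rbind(c(1L, 0L), c(1L, 5L), c(2L, 0L))
  colnames(counts) <- c("S1", "S2")
  ms <- structure(list(
    motus = data.frame(motu_id = c("M1", "M2", "M3"),
                       centroid_fwd = c("AA", "CC", "GG"),
                       centroid_rev = NA_character_,
                       total = as.integer(rowSums(counts)),
                       stringsAsFactors = FALSE),
    counts = counts, members = list(M1 = "r1", M2 = c("r2", "r3", "r4", "r5",
                                                      "r6", "r7"),
                                    M3 = c("r8", "r9"))),
    class = "motu_set")
  got <- remove_singletons(ms)
  # M1 {S1:1} dropped; M2 {S1:1,S2:5} -> {0,5}; M3 {S1:2} unchanged
  expect_equal(got$motus$motu_id, c("M2", "M3"))
  expect_equal(unname(got$counts[1, ]), c(0L, 5L))
  expect_equal(unname(got$counts[2, ]), c(2L, 0L))
  tot <- remove_singletons(ms, mode = "total")
  expect_equal(tot$motus$motu_id, c("M2", "M3")) # only total==1 dropped
  expect_equal(unname(tot$counts[1, ]), c(1L, 5L))
})

test_that("chimera screen: forced clean cases", {
  withr::with_seed(61, {
    a <- random_seq(300)
    # query equal to an abundant parent -> clean (100% single parent)
    u <- dereplicate(c(rep(a, 10), a))
    calls <- detect_chimeras(u)
    expect_true(all(calls$verdict == "clean"))
    # most-abundant unique has no eligible parents -> clean
    b <- mutate_random(a, 30)
    u2 <- dereplicate(c(rep(a, 10), rep(b, 3)))
    calls2 <- detect_chimeras(u2)
    expect_equal(calls2$verdict[1], "clean")
  })
})

test_that("chimera screen recovers injected splices with their breakpoints", {
  withr::with_seed(62, {
    a <- random_seq(300)
    b <- mutate_stratified(a, every = 10) # ~10% divergence, evenly spread
    for (true_bk in c(60, 120, 200)) {
      chim <- paste0(substr(a, 1, true_bk),
                     substr(b, true_bk + 1, nchar(b)))
      u <- dereplicate(c(rep(a, 10), rep(b, 10), chim))
      calls <- detect_chimeras(u)
      call <- calls[calls$query == which(u$sequence == chim), ]
      expect_equal(call$verdict, "chimeric")
      expect_lte(abs(call$breakpoint - true_bk), 5)
      # parents identified as the two designed sequences
      expect_setequal(u$sequence[c(call$parent_a, call$parent_b)], c(a, b))
      # exhaustive breakpoint-scan oracle: the reported model identity is
      # the max over all breakpoints of the spliced-model identity
      best <- max(vapply(30:270, function(k) {
        model <- paste0(substr(a, 1, k), substr(b, k + 1, nchar(b)))
        sum(strsplit(model, "")[[1]] == strsplit(chim, "")[[1]])
      }, numeric(1)))
      expect_equal(call$model_identity_pct, 100 * best / 300)
    }
  })
})

test_that("chimera verdicts respect the abundance skew rule", {
  withr::with_seed(63, {
    a <- random_seq(300)
    b <- mutate_stratified(a, every = 10)
    chim <- paste0(substr(a, 1, 150), substr(b, 151, 300))
    # parents only 1x as abundant as the query -> not eligible -> clean
    u <- dereplicate(c(a, b, chim))
    calls <- detect_chimeras(u, skew = 2)
    expect_true(all(calls$verdict == "clean"))
  })
})
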