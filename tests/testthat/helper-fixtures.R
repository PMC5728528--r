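# Shared in-code fixtures for the test suite.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Mutate `seq` at `n_mut` uniformly random positions (substitutions only).
mutate_random <- function(seq, n_mut) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), n_mut)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# Mutate at evenly spaced positions: one site per `every` nt, exactly
# `every` apart. Consecutive divergent sites then bracket any chimera
# breakpoint within a window of width `every`, so the plateau-midpoint
# breakpoint estimate is within `every`/2 nt of the truth by construction.
mutate_stratified <- function(seq, every = 10) {
  chars <- strsplit(seq, "")[[1]]
  pos <- seq(ceiling(every / 2), length(chars), by = every)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# A small shared classification library: 2 families x 2 genera x 2 species
# in each of three orders (Lepidoptera hosts, Hymenoptera/Diptera
# parasitoids).
tiny_library <- function(seed = 42) {
  generate_reference_library(6, 2, 2, seed = seed)
}

tiny_fallback <- function(seed = 43) generate_fallback_library(seed)

tiny_design <- function(seed = 44, ...) {
  build_mock_design(tiny_library(), tiny_fallback(), seed = seed, ...)
}

make_qual <- function(qints) intToUtf8(qints + 33L)

# Dual- vs single-read genus accuracy benchmark with congeneric-style
# confounders: for half the query species a confounder reference from a
# sibling genus shares the forward-read region verbatim but diverges ~8% in
# the reverse-read region. Forward-only classification cannot separate the
# two (exact rank tie -> family-level call); the reverse mate disambiguates.
dual_single_benchmark <- function(fx, n_queries, seed, read_len = 250) {
  withr::with_seed(seed, {
    lib <- fx$lib
    lins <- lapply(lib$taxonomy, parse_lineage)
    fam_of <- vapply(lins, `[`, character(1), 5)
    gen_of <- vapply(lins, `[`, character(1), 7)
    L <- nchar(lib$sequence[1])
    conf_rows <- list()
    confounded <- sample(seq_len(nrow(lib)), nrow(lib) %/% 2)
    for (i in confounded) {
      sib <- setdiff(which(fam_of == fam_of[i] & gen_of != gen_of[i]),
                     i)[1]
      if (is.na(sib)) next
      tail_len <- L - read_len
      conf_seq <- paste0(substr(lib$sequence[i], 1, read_len),
                         mutate_random(substr(lib$sequence[i], read_len + 1, L),
                                       round(0.08 * tail_len)))
      conf_lin <- as.character(lins[[i]])
      conf_lin[7] <- gen_of[sib]
      conf_lin[8] <- paste0(gen_of[sib], "_conf", i)
      conf_rows[[length(conf_rows) + 1]] <- data.frame(
        record_id = paste0("CONF", i), taxonomy = format_lineage(conf_lin),
        sequence = conf_seq, source = "simulated", stringsAsFactors = FALSE)
    }
    ref <- build_ref_index(rbind(lib, do.call(rbind, conf_rows)))
    dual_ok <- single_ok <- logical(n_queries)
    for (q in seq_len(n_queries)) {
      i <- sample(seq_len(nrow(lib)), 1)
      amp <- mutate_random(lib$sequence[i], 2) # conspecific variant
      fwd <- substr(amp, 1, read_len)
      rev <- revcomp(substr(amp, L - read_len + 1, L))
      truth_genus <- gen_of[i]
      d <- dual_read_assign(fwd, rev, ref)
      s <- dual_read_assign(fwd, NA, ref)
      dual_ok[q] <- length(d$lineage) >= 7 && d$lineage[[7]] == truth_genus
      single_ok[q] <- length(s$lineage) >= 7 && s$lineage[[7]] == truth_genus
    }
    list(dual = mean(dual_ok), single = mean(single_ok))
  })
}

# round-half-up at given digits (vectorized), for printed-precision checks
round_half_up_vec <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}
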