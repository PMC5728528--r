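#' @title Synthetic data generation
#' @description Generators for reference libraries, mock-community designs
#'   and error-bearing non-overlapping paired reads with full ground truth.
#'   Defaults emulate the benchmark setting the package targets: five mock
#'   samples, a dominant host (~0.8 of reads per sample, mirroring the 82.7%
#'   observed share), many low-abundance parasitoids, a bacterial symbiont
#'   fraction (~0.05) and sparse contaminants, 2x300 bp reads over a 658-nt
#'   amplicon, and linearly decaying base quality (Q38 down to Q20).
#' @name synthetic-data
NULL

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitute each given position with a different random base.
mutate_at <- function(seq, positions) {
  if (length(positions) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  chars[positions] <- vapply(chars[positions], function(b) {
    sample(setdiff(DNA_BASES, b), 1)
  }, character(1))
  paste(chars, collapse = "")
}

hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  sum(va != vb)
}

#' Generate a hierarchically structured COI-like reference library
#'
#' One 658-nt sequence per species, produced by mutating a random family
#' ancestor at disjoint position sets: each genus receives
#' `genus_divergence` private sites and each species `species_divergence`
#' private sites, so pairwise divergence is stratified by construction
#' (congeneric species ~2x`species_divergence`, confamilial genera at least
#' 2x`genus_divergence`, cross-family essentially random). Optional
#' conspecific replicates diverge by less than 1%.
#'
#' @param n_families,genera_per_family,species_per_genus Counts (>= 1).
#' @param seed Integer seed; identical seeds give identical libraries.
#' @param orders Order names cycled across families (hosts are expected in
#'   Lepidoptera, parasitoids in Hymenoptera/Diptera downstream).
#' @param seq_length Amplicon length in nt (default 658, the COI barcode).
#' @param genus_divergence,species_divergence Per-level private-site
#'   fractions (defaults 0.09 and 0.04 give congeneric divergence ~8%,
#'   within the 5-12% stratum, and cross-genus >= 18%).
#' @param replicates_per_species Extra conspecific records per species
#'   (divergence < 1%), default 0.
#' @return Data frame with `record_id`, `taxonomy` (semicolon lineage),
#'   `sequence`, `source` (= "simulated").
#' @export
generate_reference_library <- function(n_families, genera_per_family,
                                       species_per_genus, seed,
                                       orders = c("Lepidoptera", "Hymenoptera",
                                                  "Diptera"),
                                       seq_length = 658,
                                       genus_divergence = 0.09,
                                       species_divergence = 0.04,
                                       replicates_per_species = 0) {
  stopifnot(n_families >= 1, genera_per_family >= 1, species_per_genus >= 1,
            seq_length >= 50)
  g_sites <- round(genus_divergence * seq_length)
  s_sites <- round(species_divergence * seq_length)
  r_sites <- max(1, round(0.004 * seq_length)) # conspecific: < 1%
  need <- genera_per_family * (g_sites + species_per_genus *
                                 (s_sites + replicates_per_species * r_sites))
  if (need > seq_length)
    stop("divergence strata unsatisfiable: need ", need,
         " disjoint mutable sites but the sequence has only ", seq_length)
  withr::with_seed(seed, {
    rows <- list()
    for (f in seq_len(n_families)) {
      ancestor <- random_dna(seq_length)
      pool <- sample.int(seq_length) # disjoint site allocation within family
      take <- function(k) {
        out <- pool[seq_len(k)]
        pool <<- pool[-seq_len(k)]
        out
      }
      ord <- orders[(f - 1) %% length(orders) + 1]
      fam <- sprintf("Family%02d", f)
      subfam <- sprintf("Subfamily%02d", f)
      for (g in seq_len(genera_per_family)) {
        genus_seq <- mutate_at(ancestor, take(g_sites))
        genus <- sprintf("Genus%02d.%02d", f, g)
        for (s in seq_len(species_per_genus)) {
          sp_seq <- mutate_at(genus_seq, take(s_sites))
          species <- sprintf("%s_sp%02d", genus, s)
          lin <- format_lineage(c("Animalia", "Arthropoda", "Insecta", ord,
                                  fam, subfam, genus, species))
          rows[[length(rows) + 1]] <- data.frame(
            record_id = sprintf("REF_F%02dG%02dS%02d", f, g, s),
            taxonomy = lin, sequence = sp_seq, source = "simulated",
            stringsAsFactors = FALSE)
          for (r in seq_len(replicates_per_species)) {
            rows[[length(rows) + 1]] <- data.frame(
              record_id = sprintf("REF_F%02dG%02dS%02dR%02d", f, g, s, r),
              taxonomy = lin, sequence = mutate_at(sp_seq, take(r_sites)),
              source = "simulated", stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a small synthetic non-target reference set
#'
#' Bacterial "symbiont" genera and non-insect contaminant records used as
#' the LCA fallback library and as non-target members of mock samples.
#' Sequences are random (unrelated to the COI library).
#'
#' @param seed Integer seed.
#' @param seq_length Sequence length, default 658.
#' @return Data frame like [generate_reference_library()], with an extra
#'   `role` column (`symbiont` or `contaminant`).
#' @export
generate_fallback_library <- function(seed, seq_length = 658) {
  lineages <- list(
    SYM_RICKETTSIA = c("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                       "Rickettsiales", "Rickettsiaceae", "Rickettsieae",
                       "Rickettsia", "Rickettsia_sp"),
    SYM_RALSTONIA = c("Bacteria", "Proteobacteria", "Betaproteobacteria",
                      "Burkholderiales", "Burkholderiaceae", "Burkholderieae",
                      "Ralstonia", "Ralstonia_sp"),
    SYM_PSEUDOMONAS = c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
                        "Pseudomonadales", "Pseudomonadaceae",
                        "Pseudomonadeae", "Pseudomonas", "Pseudomonas_sp"),
    CONT_SOLANUM = c("Plantae", "Tracheophyta", "Magnoliopsida", "Solanales",
                     "Solanaceae", "Solanoideae", "Solanum",
                     "Solanum_lycopersicum"),
    CONT_CHRYSOMELID = c("Animalia", "Arthropoda", "Insecta", "Coleoptera",
                         "Chrysomelidae", "Chrysomelinae", "Chrysomela",
                         "Chrysomela_sp"))
  roles <- c(rep("symbiont", 3), rep("contaminant", 2))
  withr::with_seed(seed, {
    data.frame(record_id = names(lineages),
               taxonomy = vapply(lineages, format_lineage, character(1)),
               sequence = vapply(seq_along(lineages),
                                 function(i) random_dna(seq_length),
                                 character(1)),
               source = "simulated", role = roles, stringsAsFactors = FALSE)
  })
}

# Random MID set with pairwise Hamming distance >= 3.
generate_mids <- function(n, width = 7, min_dist = 3, max_tries = 10000) {
  mids <- character()
  tries <- 0
  while (length(mids) < n) {
    cand <- random_dna(width)
    if (all(vapply(mids, function(m) hamming(m, cand) >= min_dist, logical(1))))
      mids <- c(mids, cand)
    tries <- tries + 1
    if (tries > max_tries) stop("could not generate ", n, " MIDs at distance ",
                                min_dist)
  }
  mids
}

#' Build a mock host-parasitoid community design
#'
#' Emulates the benchmark layout: `n_samples` samples, each dominated by one
#' host specimen (`host_share` of reads), a few low-abundance parasitoid
#' specimens splitting the remainder, plus a bacterial symbiont fraction and
#' a small contaminant fraction. Host taxa are drawn from `host_orders`
#' records of `library`, parasitoids from `parasitoid_orders`; specimen
#' barcodes diverge from their reference by `specimen_divergence` (< 1%,
#' conspecific variation).
#'
#' @param library Reference library data frame
#'   ([generate_reference_library()]).
#' @param fallback Non-target reference set ([generate_fallback_library()]),
#'   source of symbiont/contaminant specimens; may be NULL when both
#'   fractions are zero.
#' @param seed Integer seed.
#' @param n_samples Number of mock samples (default 5).
#' @param n_host_taxa Distinct host taxa (default 4; hosts recur across
#'   samples as in the benchmark, where samples shared a host species).
#' @param n_parasitoid_taxa Distinct parasitoid taxa (default 10, for 14
#'   designed insect taxa in total).
#' @param n_parasitoid_specimens Total parasitoid individuals (default 17,
#'   for 22 individuals overall).
#' @param host_share Host read fraction per sample (default 0.8).
#' @param symbiont_fraction,contaminant_fraction Non-target read fractions
#'   per sample (defaults 0.05 and 0.02).
#' @param specimen_divergence Conspecific barcode divergence (default 0.003).
#' @param host_orders,parasitoid_orders Order names defining the guilds.
#' @return Object of class `mock_design`: list with `samples` (sample_id,
#'   mid), `specimens` (specimen_id, sample_id, role, taxon_id,
#'   relative_abundance), `barcodes` (specimen_id -> 658-nt variant),
#'   `lineages` (taxon_id -> serialized lineage).
#' @export
build_mock_design <- function(library, fallback = NULL, seed,
                              n_samples = 5, n_host_taxa = 4,
                              n_parasitoid_taxa = 10,
                              n_parasitoid_specimens = 17,
                              host_share = 0.8, symbiont_fraction = 0.05,
                              contaminant_fraction = 0.02,
                              specimen_divergence = 0.003,
                              host_orders = "Lepidoptera",
                              parasitoid_orders = c("Hymenoptera", "Diptera")) {
  stopifnot(n_samples >= 1, n_host_taxa >= 1, n_parasitoid_taxa >= 1,
            n_parasitoid_specimens >= n_samples,
            host_share > 0, host_share < 1)
  get_order <- function(tax) vapply(tax, function(t) parse_lineage(t)[4],
                                    character(1), USE.NAMES = FALSE)
  lib_orders <- get_order(library$taxonomy)
  host_pool <- library$record_id[lib_orders %in% host_orders]
  para_pool <- library$record_id[lib_orders %in% parasitoid_orders]
  if (length(host_pool) < n_host_taxa)
    stop("library has only ", length(host_pool), " host-order records; ",
         n_host_taxa, " host taxa requested")
  if (length(para_pool) < n_parasitoid_taxa)
    stop("library has only ", length(para_pool), " parasitoid-order records; ",
         n_parasitoid_taxa, " parasitoid taxa requested")
  need_fallback <- symbiont_fraction > 0 || contaminant_fraction > 0
  if (need_fallback && is.null(fallback))
    stop("fallback library required when symbiont or contaminant fractions are > 0")

  withr::with_seed(seed, {
    mids <- generate_mids(n_samples)
    sample_ids <- sprintf("S%d", seq_len(n_samples))
    host_taxa <- sample(host_pool, n_host_taxa)
    para_taxa <- sample(para_pool, n_parasitoid_taxa)
    host_of_sample <- rep(host_taxa, length.out = n_samples)
    para_counts <- rep(n_parasitoid_specimens %/% n_samples, n_samples)
    extra <- n_parasitoid_specimens - sum(para_counts)
    if (extra > 0) para_counts[seq_len(extra)] <- para_counts[seq_len(extra)] + 1
    para_assign <- rep(para_taxa, length.out = n_parasitoid_specimens)

    all_refs <- rbind(library[c("record_id", "taxonomy", "sequence")],
                      if (!is.null(fallback))
                        fallback[c("record_id", "taxonomy", "sequence")])
    seq_of <- setNames(all_refs$sequence, all_refs$record_id)
    lin_of <- setNames(all_refs$taxonomy, all_refs$record_id)

    specimens <- list()
    barcodes <- character()
    used_taxa <- character()
    k <- 0
    add_specimen <- function(sample_id, role, taxon_id, abundance) {
      k <<- k + 1
      sid <- sprintf("SP%03d_%s", k, role)
      n_mut <- round(specimen_divergence * nchar(seq_of[[taxon_id]]))
      variant <- mutate_at(seq_of[[taxon_id]],
                           sample.int(nchar(seq_of[[taxon_id]]), n_mut))
      barcodes[[sid]] <<- variant
      used_taxa <<- union(used_taxa, taxon_id)
      specimens[[length(specimens) + 1]] <<- data.frame(
        specimen_id = sid, sample_id = sample_id, role = role,
        taxon_id = taxon_id, relative_abundance = abundance,
        stringsAsFactors = FALSE)
    }
    sym_refs <- if (need_fallback) fallback$record_id[fallback$role == "symbiont"]
    cont_refs <- if (need_fallback) fallback$record_id[fallback$role == "contaminant"]
    p <- 0
    for (i in seq_len(n_samples)) {
      para_share <- 1 - host_share - symbiont_fraction - contaminant_fraction
      stopifnot(para_share > 0)
      add_specimen(sample_ids[i], "host", host_of_sample[i], host_share)
      n_p <- para_counts[i]
      for (j in seq_len(n_p)) {
        p <- p + 1
        add_specimen(sample_ids[i], "parasitoid", para_assign[p],
                     para_share / n_p)
      }
      if (symbiont_fraction > 0)
        add_specimen(sample_ids[i], "symbiont",
                     sym_refs[(i - 1) %% length(sym_refs) + 1],
                     symbiont_fraction)
      if (contaminant_fraction > 0)
        add_specimen(sample_ids[i], "contaminant",
                     cont_refs[(i - 1) %% length(cont_refs) + 1],
                     contaminant_fraction)
    }
    design <- structure(list(
      samples = data.frame(sample_id = sample_ids, mid = mids,
                           stringsAsFactors = FALSE),
      specimens = do.call(rbind, specimens),
      barcodes = barcodes,
      lineages = lin_of[used_taxa]), class = "mock_design")
    validate_mock_design(design)
    design
  })
}

#' Validate a mock design's invariants
#'
#' MIDs unique with pairwise Hamming distance >= 3, per-sample abundances
#' summing to 1 within 1e-9, and at least one host per sample.
#'
#' @param design A `mock_design`.
#' @return The design, invisibly; errors on violation.
#' @export
validate_mock_design <- function(design) {
  mids <- design$samples$mid
  stopifnot(!anyDuplicated(mids), all(nchar(mids) == nchar(mids[1])))
  if (length(mids) > 1) {
    for (i in seq_len(length(mids) - 1))
      for (j in (i + 1):length(mids))
        if (hamming(mids[i], mids[j]) < 3)
          stop("MIDs ", mids[i], " and ", mids[j], " are at Hamming distance < 3")
  }
  sums <- tapply(design$specimens$relative_abundance,
                 design$specimens$sample_id, sum)
  if (any(abs(sums - 1) > 1e-9))
    stop("per-sample relative abundances do not sum to 1")
  hosts <- tapply(design$specimens$role == "host",
                  design$specimens$sample_id, any)
  if (!all(hosts)) stop("every sample needs at least one host specimen")
  invisible(design)
}

apply_substitutions <- function(bases, error_rate) {
  if (error_rate <= 0) return(bases)
  n_err <- rbinom(length(bases), nchar(bases), error_rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(nchar(bases[i]), n_err[i])
    bases[i] <- mutate_at(bases[i], pos)
  }
  bases
}

# Linear phred decay Q38 -> Q20 with +/-3 per-base jitter, clamped to [2,41].
quality_strings <- function(n_reads, read_len) {
  profile <- round(seq(38, 20, length.out = read_len))
  jitter <- matrix(sample.int(7, n_reads * read_len, replace = TRUE) - 4L,
                   nrow = n_reads)
  q <- sweep(jitter, 2, profile, "+")
  q[q < 2] <- 2L
  q[q > 41] <- 41L
  vapply(seq_len(n_reads), function(i) int_to_qual(q[i, ]), character(1))
}

#' Simulate non-overlapping paired reads from a mock design
#'
#' The forward read is the sample MID followed by the 5' region of the
#' specimen amplicon; the reverse read is the reverse complement of the 3'
#' region. Since `2 * read_len < amplicon length`, the mates never overlap.
#' Per-read specimen identity is multinomial in the design abundances;
#' substitution errors are applied per base at `error_rate`; a
#' `chimera_rate` fraction of reads are two-parent intra-sample splices at a
#' uniform breakpoint inside the forward-read window (so the junction is
#' observable by the downstream de-novo screen), flagged in the manifest.
#'
#' @param design A [build_mock_design()] result.
#' @param reads_per_sample Pairs per sample (default 4000).
#' @param read_len Read length in nt including the MID on the forward read
#'   (default 300).
#' @param error_rate Per-base substitution probability (default 0.001).
#' @param chimera_rate Fraction of chimeric reads (default 0).
#' @param seed Integer seed.
#' @param min_segment Minimum chimera parent segment inside the forward
#'   window (default 30 nt).
#' @return List with `fwd` and `rev` read data frames (`read_id`, `bases`,
#'   `quals`) and `manifest` (`read_id`, `specimen_id`, `sample_id`,
#'   `is_chimera`, `parent_a`, `parent_b`, `breakpoint`).
#' @export
simulate_paired_reads <- function(design, reads_per_sample = 4000,
                                  read_len = 300, error_rate = 0.001,
                                  chimera_rate = 0, seed, min_segment = 30) {
  stopifnot(inherits(design, "mock_design"), reads_per_sample >= 1,
            error_rate >= 0, error_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1)
  if (nrow(design$specimens) == 0) stop("empty design")
  amp_len <- nchar(design$barcodes)
  if (any(2 * read_len >= amp_len))
    stop("2 * read_len must be smaller than the amplicon length ",
         "(non-overlapping mates)")
  mid_len <- nchar(design$samples$mid[1])
  fwd_window <- read_len - mid_len

  withr::with_seed(seed, {
    out_f <- list(); out_r <- list(); out_m <- list()
    for (si in seq_len(nrow(design$samples))) {
      sid <- design$samples$sample_id[si]
      mid <- design$samples$mid[si]
      sp <- design$specimens[design$specimens$sample_id == sid, ]
      n <- reads_per_sample
      is_chim <- runif(n) < chimera_rate & nrow(sp) >= 2
      read_ids <- sprintf("%s_read%06d", sid, seq_len(n))

      pick <- sample(sp$specimen_id, n, replace = TRUE,
                     prob = sp$relative_abundance)
      amp <- unname(design$barcodes[pick])
      specimen <- pick
      parent_a <- parent_b <- rep(NA_character_, n)
      breakpoint <- rep(NA_integer_, n)
      if (any(is_chim)) {
        for (i in which(is_chim)) {
          pa <- sample(sp$specimen_id, 2, replace = FALSE,
                       prob = sp$relative_abundance)
          b <- sample(seq(min_segment, fwd_window - min_segment), 1)
          la <- design$barcodes[[pa[1]]]
          lb <- design$barcodes[[pa[2]]]
          amp[i] <- paste0(substr(la, 1, b), substr(lb, b + 1, nchar(lb)))
          parent_a[i] <- pa[1]; parent_b[i] <- pa[2]
          breakpoint[i] <- b
          specimen[i] <- NA_character_
        }
      }
      f_bases <- paste0(mid, substr(amp, 1, fwd_window))
      r_bases <- revcomp(substr(amp, nchar(amp) - read_len + 1, nchar(amp)))
      f_bases <- apply_substitutions(f_bases, error_rate)
      r_bases <- apply_substitutions(r_bases, error_rate)
      out_f[[si]] <- data.frame(read_id = read_ids, bases = f_bases,
                                quals = quality_strings(n, read_len),
                                stringsAsFactors = FALSE)
      out_r[[si]] <- data.frame(read_id = read_ids, bases = r_bases,
                                quals = quality_strings(n, read_len),
                                stringsAsFactors = FALSE)
      out_m[[si]] <- data.frame(read_id = read_ids, specimen_id = specimen,
                                sample_id = sid, is_chimera = is_chim,
                                parent_a = parent_a, parent_b = parent_b,
                                breakpoint = breakpoint,
                                stringsAsFactors = FALSE)
    }
    list(fwd = do.call(rbind, out_f), rev = do.call(rbind, out_r),
         manifest = do.call(rbind, out_m))
  })
}
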