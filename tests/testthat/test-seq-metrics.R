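test_that("p-distance counts differing gap-free columns", {
  expect_equal(p_distance("ACDEF", "ACDEF")$p_distance, 0)
  r <- p_distance("ACDEF", "ACDEY")
  expect_equal(r$p_distance, 0.2)
  expect_equal(r$sites_used, 5)
  # gapped columns are excluded in either sequence (complete deletion)
  g <- p_distance("AC-EF", "ACD-F")
  expect_equal(g$sites_used, 3)
  expect_equal(g$p_distance, 0)
  expect_error(p_distance("ACD", "AC"), "equal length")
  expect_error(p_distance("---", "AC-"), "no gap-free")
})

test_that("p-distance matches a column-by-column brute-force oracle", {
  set.seed(41)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  a <- sample(c(aa, "-"), 120, replace = TRUE, prob = c(rep(1, 20), 2))
  b <- sample(c(aa, "-"), 120, replace = TRUE, prob = c(rep(1, 20), 2))
  r <- p_distance(paste(a, collapse = ""), paste(b, collapse = ""))
  used <- a != "-" & b != "-"
  expect_equal(r$sites_used, sum(used))
  expect_equal(r$n_diff, sum(a[used] != b[used]))
  expect_equal(r$p_distance, sum(a[used] != b[used]) / sum(used))
})

test_that("the packaged JTT model is a valid reversible rate matrix", {
  jm <- jtt_model()
  expect_equal(rowSums(jm$Q), rep(0, 20), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(-sum(jm$pi * diag(jm$Q)), 1, tolerance = 1e-12)
  flux <- jm$pi * jm$Q
  expect_equal(flux, t(flux), tolerance = 1e-12)   # detailed balance
  expect_equal(jtt_transition_prob(0), diag(20), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (d in c(0.05, 0.5, 2, 10)) {
    P <- jtt_transition_prob(d)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(P >= 0))
  }
})

test_that("JTT ML distance recovers simulated truth and its small-d limit", {
  expect_equal(jtt_distance("ACDEF", "ACDEF")$jtt_distance, 0)
  pr <- simulate_jtt_pair(10000, 0.5, seed = 7)
  d <- jtt_distance(pr$seq_a, pr$seq_b)
  expect_true(d$converged)
  expect_lt(abs(d$jtt_distance - 0.5), 3 * d$se)
  expect_gt(d$jtt_distance, d$p_distance)  # correction inflates
  # d -> 0: the ML distance approaches the raw p-distance
  pr2 <- simulate_jtt_pair(10000, 0.01, seed = 3)
  d2 <- jtt_distance(pr2$seq_a, pr2$seq_b)
  expect_lt(abs(d2$jtt_distance - d2$p_distance) / d2$p_distance, 0.10)
})

test_that("JTT ML distance agrees with an independent phylogenetics implementation", {
  skip_if_not_installed("phangorn")
  pr <- simulate_jtt_pair(4000, 0.8, seed = 13)
  mine <- jtt_distance(pr$seq_a, pr$seq_b)$jtt_distance
  aln <- phangorn::phyDat(rbind(a = strsplit(pr$seq_a, "")[[1]],
                                b = strsplit(pr$seq_b, "")[[1]]),
                          type = "AA")
  ref <- as.numeric(phangorn::dist.ml(aln, model = "JTT"))
  expect_equal(mine, ref, tolerance = 1e-4)
})

test_that("estimated distance is monotone in observed divergence", {
  ds <- c(0.05, 0.2, 0.5, 0.9, 1.4)
  res <- purrr::map_dfr(seq_along(ds), function(i) {
    pr <- simulate_jtt_pair(3000, ds[i], seed = 50 + i)
    jtt_distance(pr$seq_a, pr$seq_b)
  })
  ord <- order(res$p_distance)
  expect_true(all(diff(res$jtt_distance[ord]) > 0))
})

test_that("relative adaptiveness follows its definition, floor and tie rules", {
  w <- relative_adaptiveness(c(AAA = 4, AAG = 2, TGG = 1))
  expect_equal(w$w[w$codon == "AAA"], 1)
  expect_equal(w$w[w$codon == "AAG"], 0.5)
  expect_equal(w$w[w$codon == "TGG"], 1)   # single-codon family
  # zero-count codons get the floor, not zero
  w2 <- relative_adaptiveness(c(GGA = 10, GGC = 0, GGG = 0, GGT = 5,
                                ATG = 1))
  expect_equal(sort(w2$w[w2$amino_acid == "G"]), c(0.01, 0.01, 0.5, 1))
  expect_error(relative_adaptiveness(c(AAA = 0, AAG = 0, ATG = 3)),
               "all-zero")
  expect_error(relative_adaptiveness(c(QQQ = 1)), "unknown codon")
})

test_that("the packaged E. coli reference set has one optimal codon per amino acid", {
  w <- cai_weights_ecoli()
  expect_equal(nrow(w), 61)
  per_aa <- split(w$w, w$amino_acid)
  expect_true(all(vapply(per_aa, function(x) sum(x == 1) == 1, logical(1))))
  expect_equal(w$w[w$codon == "ATG"], 1)
  expect_equal(w$w[w$codon == "TGG"], 1)
  expect_true(all(w$w > 0 & w$w <= 1))
})

test_that("CAI is the geometric mean of w over informative codons", {
  w <- cai_weights_ecoli()
  # gene of nothing but optimal codons
  optimal <- dplyr::slice_max(dplyr::group_by(w, amino_acid), w, n = 1)
  gene <- paste(rep(optimal$codon, 3), collapse = "")
  expect_equal(platefit::cai(gene)$cai, 1.0)
  # two-codon toy gene with custom weights: sqrt(0.5 * 0.125) = 0.25
  toy_w <- tibble::tibble(codon = c("GCA", "GCC"), amino_acid = "A",
                          w = c(0.5, 0.125))
  expect_equal(platefit::cai("GCAGCC", w = toy_w)$cai, 0.25)
  # brute-force log-sum oracle on a random 120-codon gene
  set.seed(43)
  cods <- sample(w$codon, 120, replace = TRUE)
  gene2 <- paste(cods, collapse = "")
  keep <- !cods %in% c("ATG", "TGG")
  oracle <- exp(sum(log(w$w[match(cods[keep], w$codon)])) / sum(keep))
  expect_equal(platefit::cai(gene2)$cai, oracle, tolerance = 1e-12)
  # invariant under synonymous reshuffling that preserves codon counts
  expect_equal(platefit::cai(paste(sample(cods), collapse = ""))$cai, oracle,
               tolerance = 1e-12)
})

test_that("CAI agrees with an independent implementation", {
  skip_if_not_installed("seqinr")
  set.seed(44)
  w <- cai_weights_ecoli()
  gene <- generate_biased_gene(200, 0.4, seed = 17)
  caitab <- NULL
  utils::data("caitab", package = "seqinr", envir = environment())
  ref <- as.numeric(seqinr::cai(seqinr::s2c(tolower(gene)), w = caitab$ec))
  expect_equal(platefit::cai(gene)$cai, ref, tolerance = 1e-12)
})

test_that("CAI flags malformed coding input", {
  expect_error(platefit::cai("ATGAA"), "divisible by 3")
  expect_warning(platefit::cai("AAATAAAAA"), "internal stop")
  expect_error(platefit::cai("AAANNNAAA"), "non-standard")
  # all-excluded gene (Met only)
  expect_error(platefit::cai("ATGATG"), "no codons left")
})

test_that("divergence works over a whole alignment against a reference", {
  set.seed(45)
  base <- simulate_jtt_pair(300, 0.3, seed = 19)
  other <- simulate_jtt_pair(300, 0.9, seed = 19)  # same ancestor, farther
  seqs <- c(Ec = base$seq_a, Pm = base$seq_b, So = other$seq_b)
  res <- protein_divergence(seqs, reference = "Ec")
  expect_equal(nrow(res), 2)
  expect_equal(res$seq_b, c("Pm", "So"))
  expect_lt(res$jtt_distance[res$seq_b == "Pm"],
            res$jtt_distance[res$seq_b == "So"])
  expect_error(protein_divergence(seqs, reference = "zz"), "not found")
  all_pairs <- protein_divergence(seqs, reference = NULL)
  expect_equal(nrow(all_pairs), 3)
})

test_that("alignment-wide complete deletion shares one site set across pairs", {
  seqs <- c(a = "ACDEF-HIK",
            b = "ACDEYGH-K",
            c = "ACNEFGHIK")
  pw <- protein_divergence(seqs, reference = "a")
  cd <- protein_divergence(seqs, reference = "a", gap_policy = "complete")
  # columns 6 and 8 are gapped somewhere: complete deletion keeps 7 sites
  expect_true(all(cd$sites_used == 7))
  # pairwise deletion keeps different site counts per pair
  expect_equal(sort(pw$sites_used), c(7, 8))
  expect_error(protein_divergence(c(a = "---A", b = "---C", c = "----"),
                                  gap_policy = "complete"),
               "no gap-free")
})
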