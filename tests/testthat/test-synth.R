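test_that("class fractions translate into exact planted gene counts", {
  cfg <- sim_config(n_genes = 1000,
                    class_fractions = c(direct_up = 0.02, direct_down = 0.01,
                                        late = 0.05, chx_response = 0.10),
                    seed = 3)
  truth <- generate_counts(cfg)$truth
  expect_equal(as.vector(table(factor(truth$class,
    levels = c("direct_up", "direct_down", "late", "chx_response", "null")))),
    c(20, 10, 50, 100, 820))
})

test_that("identical config and seed give bit-identical output", {
  cfg <- sim_config(n_genes = 200, seed = 42)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(as.character(a$promoters), as.character(b$promoters))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(class_fractions = c(direct_up = 0.6,
    direct_down = 0.3, late = 0.2, chx_response = 0.1)), "sum")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(promoter_length = 10), "promoter_length")
  expect_error(sim_config(planted_mismatches = 5), "planted_mismatches")
  expect_error(sim_config(mean_log_range = c(5, 2)), "low <= high")
})

test_that("planted fold change appears in group means in the Poisson limit", {
  cfg <- sim_config(n_genes = 200, effect_lfc = 3, dispersion = 1e-6,
                    mean_log_range = c(log(5000), log(5000)), seed = 9)
  sim <- generate_counts(cfg)
  cm <- sim$matrix
  du <- sim$truth$gene_id[sim$truth$class == "direct_up"]
  m_th <- rowMeans(cm$counts[du, cm$condition == "TH", drop = FALSE])
  m_ctrl <- rowMeans(cm$counts[du, cm$condition == "control", drop = FALSE])
  expect_true(all(abs(log2(m_th / m_ctrl) - 3) < 0.2))
})

test_that("simulated null genes obey var = mu + alpha mu^2 within 15%", {
  alpha <- 0.1; mu <- 300
  cfg <- sim_config(n_genes = 1500, dispersion = alpha,
                    class_fractions = c(direct_up = 0, direct_down = 0,
                                        late = 0, chx_response = 0),
                    mean_log_range = c(log(mu), log(mu)), seed = 5)
  cm <- generate_counts(cfg)$matrix
  v <- mean(apply(cm$counts, 1, var))
  expect_lt(abs(v / (mu + alpha * mu^2) - 1), 0.15)
})

test_that("planted promoters carry the element exactly as recorded", {
  cfg <- sim_config(n_genes = 100, planted_mismatches = 0, seed = 11)
  sim <- simulate_experiment(cfg)
  tr <- sim$truth[sim$truth$class %in% c("direct_up", "direct_down"), ]
  expect_true(nrow(tr) > 0)
  for (i in seq_len(nrow(tr))) {
    prom <- as.character(sim$promoters[[tr$gene_id[i]]])
    win <- substr(prom, tr$tre_pos[i] + 1, tr$tre_pos[i] + 16)
    onstrand <- if (tr$tre_strand[i] == "+") win else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
    expect_identical(onstrand, tr$tre_seq[i])
    # zero planted mismatches: both half-sites read AGGTCA
    expect_identical(substr(onstrand, 1, 6), "AGGTCA")
    expect_identical(substr(onstrand, 11, 16), "AGGTCA")
  }
  # null promoters carry no bias: hit count equals the brute-force oracle's
  nullg <- sim$truth$gene_id[sim$truth$class == "null"][1]
  s <- as.character(sim$promoters[[nullg]])
  got <- scan_promoter(s, scan_config(max_mismatch = 0))
  expect_equal(nrow(got), nrow(oracle_scan(s, budget = 0)))
})

test_that("a 16-bp promoter forces the planted element to position 0", {
  cfg <- sim_config(n_genes = 50, promoter_length = 16,
                    class_fractions = c(direct_up = 0.1, direct_down = 0,
                                        late = 0, chx_response = 0),
                    seed = 2)
  sim <- simulate_experiment(cfg)
  tr <- sim$truth[sim$truth$class == "direct_up", ]
  expect_true(all(tr$tre_pos == 0))
})

test_that("planted mismatches stay within budget and off the spacer", {
  for (mm in 0:4) {
    cfg <- sim_config(n_genes = 60, planted_mismatches = mm, seed = 20 + mm,
                      class_fractions = c(direct_up = 0.2, direct_down = 0.1,
                                          late = 0, chx_response = 0))
    sim <- simulate_experiment(cfg)
    tr <- sim$truth[!is.na(sim$truth$tre_seq), ]
    half <- c(1:6, 11:16)
    pat <- strsplit("AGGTCANNNNAGGTCA", "")[[1]]
    for (el in tr$tre_seq) {
      ec <- strsplit(el, "")[[1]]
      expect_equal(sum(ec[half] != pat[half]), mm)
    }
    # recoverable by the scanner at budget = planted mismatches
    hits <- scan_set(sim$promoters[tr$gene_id],
                     scan_config(max_mismatch = mm), mode = "all_hits")
    found <- mapply(function(g, p, s)
      any(hits$gene_id == g & hits$start == p & hits$strand == s),
      tr$gene_id, tr$tre_pos, tr$tre_strand)
    expect_true(all(found))
  }
})

test_that("simulation round-trips through the TSV/FASTA writers", {
  cfg <- sim_config(n_genes = 40, seed = 6)
  sim <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  cm2 <- read_count_matrix(file.path(dir, "counts.tsv"),
                           file.path(dir, "conditions.tsv"),
                           file.path(dir, "gene_lengths.tsv"))
  expect_identical(cm2$counts, sim$matrix$counts)
  expect_identical(cm2$condition, sim$matrix$condition)
  expect_identical(cm2$gene_length, sim$matrix$gene_length)
  proms <- read_fasta(file.path(dir, "promoters.fasta"))
  expect_identical(as.character(proms), as.character(sim$promoters))
})
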