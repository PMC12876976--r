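# Brute-force average-states site scorer, independent of the package's
# lookup-table implementation.
brute_pdist <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  keep <- ca != "N" & cb != "N"
  if (!any(keep)) return(NaN)
  site <- function(x, y) {
    if (x == y) return(0)
    rx <- iupac_bases(x)
    ry <- iupac_bases(y)
    tot <- 0
    for (u in rx) for (v in ry) tot <- tot + (u != v)
    tot / (length(rx) * length(ry))
  }
  mean(mapply(site, ca[keep], cb[keep]))
}

test_that("identical strings within a class collapse into one MLG", {
  calls <- call_genotypes(dplyr::bind_rows(
    counts_row("i1", "m1", nA = 50L),
    counts_row("i1", "m2", nA = 40L, nG = 40L),
    counts_row("i2", "m1", nA = 50L),
    counts_row("i2", "m2", nA = 40L, nG = 40L),
    counts_row("i3", "m1", nA = 50L),
    counts_row("i3", "m2", nA = 40L, nG = 40L),
    counts_row("i4", "m1", nA = 50L),
    counts_row("i4", "m2", nA = 80L)
  ))
  panel <- tibble::tibble(snp = c("s1", "s2"), marker = c("m1", "m2"), pos = 1L)
  meta <- tibble::tibble(
    individual = c("i1", "i2", "i3", "i4"),
    taxon = c("LR", "LR", "LR", "LR"),
    popsys = c("L-E", "R-E", "L-E", "L-E")
  )
  m <- build_mlgs(calls, panel, meta)
  expect_equal(nrow(m), 2)
  shared <- m[m$sequence == "AR", ]
  expect_equal(shared$multiplicity, 3L)
  expect_equal(shared$popsys, "L-E,R-E") # shared between two systems
  # a string differing only by N is a distinct MLG
  calls2 <- dplyr::bind_rows(
    calls,
    call_genotypes(counts_row("i5", "m1", nA = 50L)) # m2 missing -> "AN"
  )
  meta2 <- dplyr::bind_rows(
    meta, tibble::tibble(individual = "i5", taxon = "LR", popsys = "L-E")
  )
  m2 <- build_mlgs(calls2, panel, meta2)
  expect_equal(nrow(m2), 3)
  expect_error(build_mlgs(calls, panel[0, ], meta), "empty")
})

test_that("MLG FASTA files round-trip", {
  m <- tibble::tibble(
    mlg_id = c("LR_MLG001", "LR_MLG002"), sequence = c("ARN", "AAT"),
    genotype = "LR", multiplicity = c(3L, 1L), popsys = c("L-E,R-E", "E")
  )
  path <- withr::local_tempfile(fileext = ".fa")
  write_mlg_fasta(m, path)
  back <- read_mlg_fasta(path)
  expect_equal(back$sequence, m$sequence)
  expect_equal(back$multiplicity, m$multiplicity)
  expect_equal(back$popsys, m$popsys)
})

test_that("ambiguity p-distance treats ambiguous sites as average states", {
  expect_equal(ambiguity_pdistance("AR", "AR"), 0) # identical codes: zero
  expect_equal(ambiguity_pdistance("A", "R"), 0.5)
  expect_equal(ambiguity_pdistance("AA", "AG"), 0.5)
  expect_equal(ambiguity_pdistance("R", "Y"), 1) # {A,G} vs {C,T}: all differ
  expect_equal(ambiguity_pdistance("ANA", "ANG"), 0.5) # N pairwise-deleted
  expect_true(is.nan(ambiguity_pdistance("N", "A")))
  expect_error(ambiguity_pdistance("AA", "A"), "length")
})

test_that("ambiguity p-distance equals brute-force resolution averaging", {
  set.seed(91)
  codes <- setdiff(names(gtseqpop:::IUPAC_RESOLUTIONS), character(0))
  for (i in 1:50) {
    L <- sample(1:10, 1)
    a <- paste(sample(codes, L, replace = TRUE), collapse = "")
    b <- paste(sample(codes, L, replace = TRUE), collapse = "")
    got <- ambiguity_pdistance(a, b)
    want <- brute_pdist(a, b)
    if (is.nan(want)) expect_true(is.nan(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("UPGMA matches hand computation and stays ultrametric", {
  d <- matrix(
    c(0, 0.2, 0.6, 0.2, 0, 0.6, 0.6, 0.6, 0), 3, 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  tr <- upgma_tree(d)
  expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  # heights: A,B join at 0.1; C attaches at 0.3
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp["A", "B"], 0.2)
  expect_equal(cp["A", "C"], 0.6)
  expect_equal(cp["B", "C"], 0.6)

  # all-zero matrix: star at height 0
  z <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tz <- upgma_tree(z)
  expect_true(all(ape::node.depth.edgelength(tz) == 0))

  # random matrices: ultrametric output, leaf set preserved
  set.seed(93)
  for (i in 1:5) {
    m <- matrix(runif(64), 8, 8)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(letters[1:8], letters[1:8])
    t8 <- upgma_tree(m)
    expect_true(ape::is.ultrametric(t8, tol = 1e-9))
    expect_setequal(t8$tip.label, letters[1:8])
  }
  expect_error(upgma_tree(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("atomic encoding maps bases to proton counts", {
  expect_equal(unname(atomic_encode("ACGT")[1, ]), c(70, 58, 78, 66))
  expect_equal(unname(atomic_encode("R")[1, 1]), 74) # mean of A, G
  expect_equal(unname(atomic_encode("W")[1, 1]), 68) # mean of A, T
  expect_true(is.na(atomic_encode("N")[1, 1]))
  expect_error(atomic_encode("AX"), "unknown")
})

test_that("stepwise LDA selects the separating variable in a clean design", {
  set.seed(95)
  X <- cbind(
    v1 = c(rnorm(20, 0), rnorm(20, 8)),
    v2 = rnorm(40), v3 = rnorm(40), v4 = rnorm(40)
  )
  y <- rep(c("a", "b"), each = 20)
  fit <- stepwise_lda(X, y)
  # the separating variable enters first and classifies perfectly; noise
  # variables can only trail it (each has the nominal ~5% entry chance)
  expect_identical(fit$selected[1], "v1")
  expect_equal(fit$accuracy, 100)
  # deterministic under a fixed variable order
  fit2 <- stepwise_lda(X, y)
  expect_identical(fit$selected, fit2$selected)
  expect_equal(fit$accuracy, fit2$accuracy)
})

test_that("stepwise LDA rarely admits variables under permuted labels", {
  # Under the null each of the 5 candidate partial-F statistics exceeds
  # the entry threshold with probability P(F(1, n-g) >= 4), so by the
  # Bonferroni bound the no-variable-selected rate is at least
  # 1 - 5 * P(F(1, 38) >= 4) ~ 0.74.
  set.seed(97)
  reps <- 200
  none <- 0
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- rep(c("a", "b"), each = 20)
  for (i in seq_len(reps)) {
    fit <- stepwise_lda(X, sample(y), f_enter = 4.0)
    none <- none + (length(fit$selected) == 0)
  }
  bound <- 1 - 5 * (1 - stats::pf(4, 1, 38))
  expect_gte(none / reps, bound - 0.05) # Monte Carlo margin
})

test_that("stepwise LDA tracks a direct eigen-solve oracle on a 3-class mixture", {
  set.seed(99)
  n <- 60
  mu <- list(c(0, 0), c(2.2, 0), c(0, 2.2))
  X <- do.call(rbind, lapply(mu, function(m) {
    cbind(rnorm(n, m[1]), rnorm(n, m[2]))
  }))
  X <- cbind(X, noise = rnorm(3 * n))
  colnames(X) <- c("x1", "x2", "noise")
  y <- rep(c("a", "b", "c"), each = n)
  fit <- stepwise_lda(X, y)
  expect_true(all(c("x1", "x2") %in% fit$selected))

  # direct Fisher solve: eigen of W^-1 B, nearest-centroid classification
  Xs <- X[, c("x1", "x2")]
  grand <- colMeans(Xs)
  W <- matrix(0, 2, 2); B <- matrix(0, 2, 2)
  for (g in unique(y)) {
    Xi <- Xs[y == g, ]
    ci <- colMeans(Xi)
    W <- W + crossprod(scale(Xi, center = ci, scale = FALSE))
    B <- B + nrow(Xi) * tcrossprod(ci - grand)
  }
  ev <- eigen(solve(W) %*% B)
  V <- Re(ev$vectors[, 1:2])
  proj <- Xs %*% V
  cent <- rowsum(proj, y) / as.vector(table(y))
  d2 <- outer(rowSums(proj^2), rowSums(cent^2), "+") - 2 * proj %*% t(cent)
  oracle_acc <- 100 * mean(rownames(cent)[apply(d2, 1, which.min)] == y)
  expect_lt(abs(fit$accuracy - oracle_acc) / 100, 0.1)
})

test_that("stepwise LDA respects max_steps and imputes missing sites", {
  set.seed(103)
  X <- matrix(rnorm(60 * 6), 60, 6)
  X[, 1] <- X[, 1] + rep(c(0, 3, 6), each = 20)
  X[, 2] <- X[, 2] + rep(c(0, 2, 4), each = 20)
  X[sample(length(X), 10)] <- NA
  y <- rep(c("a", "b", "c"), each = 20)
  expect_message(fit <- stepwise_lda(X, y, max_steps = 1), "imputing")
  expect_length(fit$selected, 1)
  expect_error(stepwise_lda(X, rep("a", 60)), "classes")
})

test_that("composite LD is one for a duplicated SNP and near zero when independent", {
  co <- parental_cohort()
  cfg <- co$config
  calls <- call_genotypes(co$counts)
  des <- tibble::tibble(
    snp = cfg$snp_panel$snp, designated = cfg$snp_panel$l_base
  )
  # dosage variance requires frequency-driven SNPs: RR cohort at f = 0.5
  eff_cfg <- one_pop_config(
    n_RR = 300, popsys = "all-R", n_snps = 16, error_rate = 0,
    coverage_mean = 100, coverage_dispersion = 1e6, seed = 105,
    popsys_effect = tidyr::crossing(
      snp = sprintf("snp%02d", 1:16),
      tibble::tibble(popsys = "all-R", f = 0.5)
    )
  )
  co2 <- cached_cohort("ld_indep", eff_cfg)
  calls2 <- call_genotypes(co2$counts)
  panel2 <- eff_cfg$snp_panel
  des3 <- tibble::tibble(snp = panel2$snp, designated = panel2$l_base)

  dup2_calls <- dplyr::bind_rows(
    calls2,
    dplyr::mutate(calls2[calls2$marker == panel2$marker[1], ],
                  marker = paste0(marker, "b"))
  )
  dup2_panel <- dplyr::bind_rows(
    panel2, dplyr::mutate(panel2[1, ], snp = "snp01b",
                          marker = paste0(marker, "b"))
  )
  des4 <- dplyr::bind_rows(
    des3, tibble::tibble(snp = "snp01b", designated = panel2$l_base[1])
  )
  self <- pairwise_ld(
    dup2_calls, co2$metadata, dup2_panel, des4, "RR",
    pairs = tibble::tibble(snp1 = "snp01", snp2 = "snp01b")
  )
  expect_equal(self$r, 1)

  # independently simulated SNPs: |r| small for nearly all pairs
  ld <- pairwise_ld(calls2, co2$metadata, panel2, des3, "RR")
  off <- ld[ld$snp1 != ld$snp2, ]
  expect_gte(mean(abs(off$r) < 0.15, na.rm = TRUE), 0.95)

  # monomorphic SNP: undefined, reported as NA
  mono <- pairwise_ld(
    calls, co$metadata, cfg$snp_panel, des, "RR",
    pairs = tibble::tibble(snp1 = "snp01", snp2 = "snp02")
  )
  expect_true(is.na(mono$r))
})

test_that("the MLG pipeline separates planted population-system clusters", {
  # four diagnostic sites with complementary system patterns; the other
  # twelve panel SNPs carry no system information for LR individuals
  eff <- dplyr::bind_rows(
    tidyr::crossing(
      tibble::tibble(snp = c("snp01", "snp02")),
      tibble::tibble(popsys = c("L-E", "R-E", "E"), f = c(0.02, 0.98, 0.5))
    ),
    tidyr::crossing(
      tibble::tibble(snp = c("snp03", "snp04")),
      tibble::tibble(popsys = c("L-E", "R-E", "E"), f = c(0.5, 0.98, 0.02))
    )
  )
  pops <- tibble::tibble(
    population = c("p1", "p2", "p3"), popsys = c("L-E", "R-E", "E"),
    region = c("a", "b", "c"), lat = c(49, 53, 54), lon = c(14, 14, 12),
    n_LL = 0, n_RR = 0, n_LR = 40, n_LLR = 0, n_RRL = 0
  )
  cfg <- sim_config(
    populations = pops, popsys_effect = eff, error_rate = 0,
    coverage_mean = 100, coverage_dispersion = 1e6, seed = 107
  )
  co <- cached_cohort("mlg_clusters", cfg)
  calls <- call_genotypes(co$counts)
  seqs <- consensus_sequences(calls, cfg$snp_panel)
  labs <- co$metadata$popsys[match(seqs$individual, co$metadata$individual)]
  X <- atomic_encode(stats::setNames(seqs$sequence, seqs$individual))
  fit <- stepwise_lda(X, labs)
  # only informative sites are admitted (redundant diagnostic sites may
  # legitimately stay out once the classes are separated)
  expect_gt(length(fit$selected), 0)
  expect_true(all(fit$selected %in% paste0("site", 1:4)))
  expect_gte(fit$accuracy, 90)
  expect_lte(length(fit$selected), 50)
})
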