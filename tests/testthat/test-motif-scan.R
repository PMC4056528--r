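# independent per-word scorer used as the oracle in this file
oracle_score <- function(pwm, word) {
  bases <- strsplit(word, "")[[1]]
  idx <- match(bases, c("A", "C", "G", "T"))
  reg <- (pwm$probs + pwm$pseudocount) / (1 + 4 * pwm$pseudocount)
  sum(log2(reg[cbind(seq_along(idx), idx)] / pwm$background[idx]))
}

all_words <- function(w) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), w),
                              stringsAsFactors = FALSE))
}

revcomp <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                    collapse = ""))

test_that("log-odds scoring: identity, closed form, strand symmetry", {
  unif <- pwm_record(matrix(0.25, 5, 4), pseudocount = 0)
  expect_equal(log_odds_score(unif, "ACGTA"), 0)
  peaked <- pwm_record(matrix(rep(c(.97, .01, .01, .01), 6), ncol = 4,
                              byrow = TRUE), pseudocount = 0)
  expect_equal(log_odds_score(peaked, "AAAAAA"), 6 * log2(.97 / .25),
               tolerance = 1e-9)
  expect_true(is.na(log_odds_score(peaked, "AANAAA")))
  # reverse-complement PWM scores the reverse complement of the word
  pwm <- default_pwm()
  rc <- pwm_revcomp(pwm)
  set.seed(61)
  for (w in sample(all_words(3), 5)) {
    word <- paste0(w, "TGTGGTA")       # width 10
    expect_equal(log_odds_score(rc, word),
                 log_odds_score(pwm, revcomp(word)), tolerance = 1e-9)
  }
})

test_that("exact p-values match exhaustive enumeration (uniform and skewed bg)", {
  set.seed(62)
  for (cfg in list(list(w = 4, bg = rep(.25, 4)),
                   list(w = 5, bg = c(.4, .1, .1, .4)),
                   list(w = 6, bg = c(.3, .2, .2, .3)))) {
    probs <- matrix(stats::rgamma(cfg$w * 4, 1), cfg$w, 4)
    probs <- probs / rowSums(probs)
    pwm <- pwm_record(probs, background = cfg$bg, pseudocount = 0.01)
    eps <- 1e-3
    pfun <- exact_score_pvalue(pwm, eps = eps)
    words <- all_words(cfg$w)
    scores <- vapply(words, oracle_score, 0, pwm = pwm)
    wprob <- vapply(words, function(wd) {
      idx <- match(strsplit(wd, "")[[1]], c("A", "C", "G", "T"))
      prod(cfg$bg[idx])
    }, 0)
    # exact tail at s: sum of bg probabilities of words scoring >= s
    for (s in sample(scores, 40)) {
      p_hi <- sum(wprob[scores >= s - cfg$w * eps])   # discretization bound
      p_lo <- sum(wprob[scores >= s + cfg$w * eps])
      p_dp <- pfun(s)
      expect_gte(p_dp, p_lo - 1e-12)
      expect_lte(p_dp, p_hi + 1e-12)
    }
    # boundary behaviour
    expect_equal(pfun(-1e6), 1)
    expect_lt(pfun(max(scores) + 1), 1e-9)
    # strict-max PWM: p at maximal score = product of bg at argmax rows
    strict <- pwm_record(matrix(rep(c(.97, .01, .01, .01), 4), ncol = 4,
                                byrow = TRUE), background = cfg$bg,
                         pseudocount = 0)
    pf2 <- exact_score_pvalue(strict, eps = eps)
    expect_equal(pf2(4 * log2(.97 / cfg$bg[1])), cfg$bg[1]^4,
                 tolerance = 1e-6)
  }
})

test_that("scan_sequences equals brute-force window scoring and finds planted sites", {
  set.seed(63)
  pwm <- default_pwm()
  seq_ <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                collapse = "")
  # plant the consensus at known offsets (0-based 2000 and 7000)
  substr(seq_, 2001, 2010) <- pwm$consensus
  substr(seq_, 7001, 7010) <- pwm$consensus
  hits <- scan_sequences(pwm, c(s = seq_), p_threshold = 1e-4)
  expect_true(all(c(2000L, 7000L) %in% hits[strand == "+", start]))
  pfun <- exact_score_pvalue(pwm)
  # brute force both strands
  rc <- pwm_revcomp(pwm)
  brute <- list()
  for (i in 1:(10000 - 10)) {
    word <- substr(seq_, i, i + 9)
    for (str in c("+", "-")) {
      s <- log_odds_score(if (str == "+") pwm else rc, word)
      if (!is.na(s) && pfun(s) < 1e-4)
        brute[[length(brute) + 1L]] <- data.table(start = i - 1L, strand = str,
                                                  score = s)
    }
  }
  brute <- rbindlist(brute)
  setorder(brute, start, strand)
  expect_equal(hits[, .(start, strand)], brute[, .(start, strand)])
  expect_equal(hits$score, brute$score, tolerance = 1e-9)
  # all-N sequence yields no hits
  expect_equal(nrow(scan_sequences(pwm, c(n = strrep("N", 500)))), 0L)
  # mirrored hit set on the reverse complement sequence
  hits_rc <- scan_sequences(pwm, c(s = revcomp(seq_)), p_threshold = 1e-4)
  expect_equal(sort(10000 - (hits$end)), sort(hits_rc$start))
})

test_that("best_site_per_peak picks highest score, breaks ties by summit distance", {
  hits <- data.table(chrom = "c", start = c(100L, 300L, 420L, 480L),
                     end = c(110L, 310L, 430L, 490L),
                     strand = "+", score = c(8.1, 9.3, 5, 5),
                     p_value = c(1e-5, 1e-6, 1e-4, 1e-4))
  pk <- peak_set(data.table(chrom = "c", start = c(50L, 400L, 900L),
                            end = c(350L, 500L, 950L),
                            summit_offset = c(150L, 90L, 10L),
                            name = c("p1", "p2", "p3")), threshold = 0)
  best <- best_site_per_peak(pk, hits)
  expect_equal(best[name == "p1", hit_score], 9.3)
  # p2 summit at 490; ties at score 5: site [480,490) center 485 is nearer
  expect_equal(best[name == "p2", hit_start], 480L)
  expect_true(is.na(best[name == "p3", hit_start]))
})

test_that("summit-distance profiles normalize per tier and order by jitter", {
  set.seed(64)
  n <- 450
  scorep <- c(rnorm(n / 3, 40, 2), rnorm(n / 3, 25, 2), rnorm(n / 3, 12, 2))
  jitter_sd <- rep(c(20, 50, 100), each = n / 3)
  summit <- sample(2000:3000, n, replace = TRUE)
  start <- summit - 150L
  d <- round(rnorm(n, 0, jitter_sd))
  hits <- data.table(name = paste0("p", 1:n),
                     hit_start = summit + d - 5L, hit_end = summit + d + 5L,
                     hit_strand = "+", hit_score = 10, hit_p = 1e-5)
  pk <- peak_set(data.table(chrom = "c", start = start, end = start + 300L,
                            summit_offset = 150L, neglog10_p = scorep,
                            name = paste0("p", 1:n)), threshold = 0)
  prof <- summit_distance_profile(pk, hits, n_tiers = 3, max_dist = 500,
                                  bin_width = 10)
  sums <- prof[, sum(probability), by = tier]
  expect_equal(sums$V1, rep(1, 3), tolerance = 1e-9)
  p0 <- prof[bin_center == 0]
  expect_gt(p0[tier == 1, probability], p0[tier == 3, probability])
  # motifs planted exactly at summits -> modal bin 0
  hits0 <- copy(hits)[, `:=`(hit_start = summit - 5L, hit_end = summit + 5L)]
  prof0 <- summit_distance_profile(pk, hits0)
  for (tt in 1:3) {
    sub <- prof0[tier == tt]
    expect_equal(sub[which.max(probability), bin_center], 0)
  }
})
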