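test_that("translation follows the standard genetic code", {
  expect_equal(as.character(translate_cds("CAGCAGGCT")), "QQA")
  expect_equal(as.character(translate_cds("ATG")), "M")
  # independent table lookup against the standard genetic code
  lookup <- Biostrings::GENETIC_CODE[c("CAA", "CAG", "CAA")]
  expect_equal(as.character(translate_cds("CAACAGCAA")), paste(lookup, collapse = ""))
  # frame offset and trailing partial codon
  expect_equal(as.character(translate_cds("TCAGCAGGCTAA", frame = 1)), "QQA")
  # ambiguous codons become X, lowercase accepted
  expect_equal(as.character(translate_cds("cagcangct")), "QXA")
})

test_that("internal stop codons are flagged, not fatal", {
  aa <- translate_cds("CAGTAAGCT")
  expect_equal(as.character(aa), "Q*A")
  expect_true(attr(aa, "internal_stop"))
  aa2 <- translate_cds("CAGGCTTAA")  # terminal stop only
  expect_false(attr(aa2, "internal_stop"))
  expect_error(translate_cds(""), "non-empty")
  expect_error(translate_cds("CAGUAG"), "alphabet")
  expect_error(translate_cds("CA"), "codon")
})

test_that("domain location between anchors matches exact coordinates", {
  cfg <- repeat_config(five_prime_anchor = "MRIPV", three_prime_anchor = "PSTSR")
  loc <- locate_qa_domain("MRIPVQQQQQAAAPSTSR", cfg)
  expect_true(loc$passed)
  expect_equal(c(loc$domain_start, loc$domain_end), c(5L, 13L))
  # exclusion rule: sequence lacking the 3' anchor fails the screen
  miss <- locate_qa_domain("MRIPVQQQQQAAAYYYYY", cfg)
  expect_false(miss$passed)
  expect_match(miss$reason, "3'")
  # both anchors present but in the wrong order is malformed, not a screen miss
  expect_error(locate_qa_domain("XXPSTSRQQQQAAAXXXXXMRIPVXX", cfg), "malformed")
})

test_that("anchor matching tolerates the configured mismatch budget", {
  cfg1 <- repeat_config(max_anchor_mismatches = 1)
  loc <- locate_qa_domain("MRIPAQQQAAAPSTSR", cfg1)
  expect_true(loc$passed)
  # sliding-window Hamming oracle
  seq_chars <- strsplit("MRIPAQQQAAAPSTSR", "")[[1]]
  hamming_hits <- function(anchor) {
    a <- strsplit(anchor, "")[[1]]
    ok <- integer(0)
    for (s in seq_len(length(seq_chars) - length(a) + 1)) {
      if (sum(seq_chars[s:(s + length(a) - 1)] != a) <= 1) ok <- c(ok, s)
    }
    ok
  }
  expect_equal(loc$domain_start, hamming_hits("MRIPV")[1] + 4L)
  expect_equal(loc$domain_end, hamming_hits("PSTSR")[1] - 1L)
  expect_equal(c(loc$domain_start, loc$domain_end), c(5L, 11L))
})

test_that("domain location is invariant to padding outside the anchors", {
  cfg <- repeat_config()
  base <- "MRIPVQQQQQAAAPSTSR"
  set.seed(42)
  for (i in 1:10) {
    left <- paste(sample(c("G", "S", "T", "P", "M"), sample(0:12, 1), TRUE), collapse = "")
    right <- paste(sample(c("G", "S", "T", "P", "M"), sample(0:12, 1), TRUE), collapse = "")
    loc <- locate_qa_domain(paste0(left, base, right), cfg)
    expect_true(loc$passed)
    expect_equal(loc$domain_end - loc$domain_start, 8L)
    expect_equal(loc$domain_start, nchar(left) + 5L)
  }
})

test_that("tandem run counting handles pure and interrupted runs", {
  cfg <- repeat_config()
  r <- count_tandem_repeats("QQQQQAAA", c(0, 8), cfg)
  expect_equal(c(r$q_count, r$a_count), c(5L, 3L))
  # interruption tolerance: exhaustive run enumeration oracle
  s <- "QQQQHQQQAAAA"
  cfg1 <- repeat_config(max_interruptions = 1)
  chars <- strsplit(s, "")[[1]]
  best <- function(target) {
    top <- 0L
    for (i in seq_along(chars)) for (j in i:length(chars)) {
      win <- chars[i:j]
      if (win[1] == target && win[length(win)] == target &&
          sum(win != target) <= 1) top <- max(top, sum(win == target))
    }
    top
  }
  r1 <- count_tandem_repeats(s, c(0, nchar(s)), cfg1)
  expect_equal(r1$q_count, best("Q"))
  expect_equal(r1$a_count, best("A"))
  expect_equal(c(r1$q_count, r1$a_count), c(7L, 4L))
  # order invariant: a polyA tract preceding the polyQ tract is malformed
  expect_error(count_tandem_repeats("AAAAQQQQ", c(0, 8), cfg), "precedes")
  # runs below the minimum length fail the screen
  short <- count_tandem_repeats("QQAAGGGG", c(0, 8), cfg)
  expect_false(short$passed)
})

test_that("qa_ratio reproduces printed ratios and is monotone", {
  expect_equal(round(qa_ratio(21, 9), 2), 2.33)
  expect_equal(round(qa_ratio(23, 17), 2), 1.35)
  for (k in c(1, 5, 17)) expect_equal(qa_ratio(k, k), 1)
  expect_equal(qa_ratio(7, 3) * 3, 7)
  expect_true(qa_ratio(8, 3) > qa_ratio(7, 3))
  expect_true(qa_ratio(7, 4) < qa_ratio(7, 3))
  expect_error(qa_ratio(5, 0), "a_count")
})

test_that("extraction round-trips synthesized sequences, protein and nucleotide", {
  set.seed(7)
  specs <- data.frame(species_id = paste0("sp", 1:12),
                      q = sample(3:30, 12, TRUE), a = sample(3:20, 12, TRUE))
  aa <- synthesize_runx2_sequences(specs)
  res <- extract_qa(aa)
  expect_true(all(res$passed_screen))
  expect_equal(res$q_count, specs$q)
  expect_equal(res$a_count, specs$a)
  expect_equal(res$qa_ratio, specs$q / specs$a)
  nt <- synthesize_runx2_sequences(specs, as_nucleotide = TRUE, seed = 11)
  res_nt <- extract_qa(nt)
  expect_equal(res_nt$q_count, specs$q)
  expect_equal(res_nt$a_count, specs$a)
  expect_true(all(res_nt$frame == 0L))
})

test_that("extraction reads FASTA files and reports screen failures", {
  specs <- data.frame(species_id = c("ok1", "ok2"), q = c(10, 4), a = c(5, 8))
  aa <- synthesize_runx2_sequences(specs)
  fa <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(aa, fa)
  res <- extract_qa(fa)
  expect_equal(res$species_id, c("ok1", "ok2"))
  expect_equal(res$qa_ratio, c(2, 0.5))
  # a record without anchors fails the screen but does not abort the batch
  res2 <- extract_qa(c(good = "MRIPVQQQQQAAAPSTSR", bad = "GGGGQQQQQAAAGGGG"))
  expect_equal(res2$passed_screen, c(TRUE, FALSE))
  expect_true(is.na(res2$qa_ratio[2]))
  audit <- attr(res2, "audit")
  expect_equal(audit$config$five_prime_anchor, "MRIPV")
  expect_false(audit$records$bad$passed)
})

test_that("repeat configuration rejects degenerate anchors", {
  expect_error(repeat_config(five_prime_anchor = ""), "non-empty")
  expect_error(repeat_config(five_prime_anchor = "QQQQQX"), "runs longer")
  expect_error(repeat_config(min_run_length = 2), "min_run_length")
})
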