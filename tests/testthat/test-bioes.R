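test_that("a five-residue motif encodes as B I I I E on its track", {
  # sequence with motif 1 spanning the subsequence SSLSA and a single-residue
  # motif 3 further downstream
  a <- annotated_sequence("MKSSLSAGTRL", data.frame(
    start = c(3, 9), end = c(7, 9),
    category = c("Motif1", "Motif3"), kind = "motif"))
  expect_equal(substr(a$sequence, 3, 7), "SSLSA")
  tags <- encode_bioes(a)$tracks$motif
  expect_equal(tags[3:7],
               c("B-Motif1", "I-Motif1", "I-Motif1", "I-Motif1", "E-Motif1"))
  expect_equal(tags[9], "S-Motif3")
  expect_equal(tags[c(1, 2, 8, 10, 11)], rep("O", 5))
})

test_that("kinds are encoded on separate tracks and may overlap", {
  a <- annotated_sequence("AAAAAAAA", data.frame(
    start = c(1, 2), end = c(4, 6),
    category = c("Motif1", "Domain2"), kind = c("motif", "domain")))
  enc <- encode_bioes(a)
  expect_equal(enc$tracks$motif[1:4],
               c("B-Motif1", "I-Motif1", "I-Motif1", "E-Motif1"))
  expect_equal(enc$tracks$domain[2:6],
               c("B-Domain2", "I-Domain2", "I-Domain2", "I-Domain2",
                 "E-Domain2"))
  expect_equal(enc$tracks$region, rep("O", 8))
  # but a single combined track rejects the overlap
  expect_error(encode_bioes(a, combine_kinds = TRUE), "overlap across kinds")
})

test_that("span invariants are enforced at construction", {
  expect_error(annotated_sequence("AAAA", data.frame(
    start = 2, end = 5, category = "x", kind = "motif")), "out of bounds")
  expect_error(annotated_sequence("AAAA", data.frame(
    start = 0, end = 2, category = "x", kind = "motif")), "out of bounds")
  expect_error(annotated_sequence("AAAAAA", data.frame(
    start = c(1, 3), end = c(3, 5), category = "x", kind = "motif")),
    "overlapping")
  # same positions on different kinds are fine
  expect_s3_class(annotated_sequence("AAAAAA", data.frame(
    start = c(1, 1), end = c(3, 3), category = "x",
    kind = c("motif", "region"))), "annotated_sequence")
})

test_that("sequences without entities are all O and tags match length", {
  a <- annotated_sequence("MKLVA")
  enc <- encode_bioes(a)
  for (track in enc$tracks) {
    expect_equal(track, rep("O", 5))
    expect_length(track, nchar(a$sequence))
  }
  expect_equal(nrow(decode_bioes(enc$tracks$motif)), 0L)
})

test_that("decoding inverts encoding and flags grammar violations", {
  expect_equal(decode_bioes(c("B-x", "E-x")),
               data.frame(start = 1L, end = 2L, category = "x"))
  expect_error(decode_bioes(c("I-x", "E-x")), "position 1")
  expect_error(decode_bioes(c("B-x", "O")), "position 2")
  expect_error(decode_bioes(c("B-x", "I-y", "E-x")), "position 2")
  expect_error(decode_bioes(c("B-x", "B-x", "E-x")), "position 2")
  expect_error(decode_bioes(c("E-x")), "position 1")
  expect_error(decode_bioes(c("B-x", "S-y", "E-x")), "position 2")
  expect_error(decode_bioes(c("O", "B-x")), "position 2")
  expect_error(decode_bioes(c("Q-x")), "malformed")
})

test_that("encode/decode roundtrips on random annotated sequences", {
  set.seed(13)
  for (rep in 1:200) {
    a <- rand_annotated_sequence(sprintf("s%d", rep))
    enc <- encode_bioes(a)
    for (kd in names(enc$tracks)) {
      spans <- decode_bioes(enc$tracks[[kd]])
      want <- a$entities[a$entities$kind == kd, c("start", "end", "category")]
      want <- want[order(want$start), ]
      rownames(want) <- rownames(spans) <- NULL
      expect_equal(spans, want)
    }
  }
})

test_that("long-tail merging thresholds categories into Other", {
  v <- merge_long_tail(c(A = 100, B = 1, C = 1), min_count = 5)
  expect_setequal(v$categories, c("A", "Other"))
  expect_equal(unname(v$mapping[c("A", "B", "C")]), c("A", "Other", "Other"))
  # all counts above threshold: vocabulary unchanged, nothing merged
  v2 <- merge_long_tail(c(A = 10, B = 7), min_count = 5)
  expect_setequal(v2$categories, c("A", "B", "Other"))
  expect_equal(unname(v2$mapping), c("A", "B"))
  # zero threshold is the identity mapping
  v3 <- merge_long_tail(c(A = 3, B = 0), min_count = 0)
  expect_equal(unname(v3$mapping), c("A", "B"))
  expect_error(merge_long_tail(c(A = -1), 2), "nonnegative")
  # retained non-Other categories all meet the threshold
  set.seed(1)
  counts <- setNames(rpois(50, 3), paste0("c", 1:50))
  v4 <- merge_long_tail(counts, min_count = 4)
  kept <- setdiff(v4$categories, "Other")
  expect_true(all(counts[kept] >= 4))
})

test_that("encoding resolves categories through a merged vocabulary", {
  vocab <- merge_long_tail(c(Motif1 = 50, Motif9 = 1), min_count = 5)
  a <- annotated_sequence("AAAAAA", data.frame(
    start = c(1, 5), end = c(3, 5),
    category = c("Motif1", "Motif9"), kind = "motif"))
  tags <- encode_bioes(a, vocab)$tracks$motif
  expect_equal(tags[1], "B-Motif1")
  expect_equal(tags[5], "S-Other")
  # a category never seen in the counts also maps to Other
  b <- annotated_sequence("AAA", data.frame(
    start = 1, end = 1, category = "Unheard", kind = "motif"))
  expect_equal(encode_bioes(b, vocab)$tracks$motif[1], "S-Other")
})

test_that("annotation TSV reading and tag writing are consistent", {
  path <- system.file("extdata", "synthetic_toy_annotations.tsv",
                      package = "otfrm")
  seqs <- read_annotations(path)
  expect_true("Q8BUZ1_like" %in% names(seqs))
  enc <- encode_bioes(seqs[["Q8BUZ1_like"]])
  expect_true("B-Motif1" %in% enc$tracks$motif)
  expect_true("E-Motif1" %in% enc$tracks$motif)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_bioes_tags(lapply(seqs, encode_bioes), out)
  df <- read.delim(out)
  expect_named(df, c("sequence_id", "position", "residue", "kind", "tag"))
  expect_equal(sum(df$sequence_id == "Q8BUZ1_like" & df$kind %in% "motif"),
               nchar(seqs[["Q8BUZ1_like"]]$sequence))
})
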