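test_that("reference MSA construction builds column maps and validates input", {
  msa <- tiny_msa()
  expect_equal(msa$L, 4L)
  expect_equal(msa$N, 2L)
  expect_equal(msa$col_map$a, 1:4)
  expect_equal(msa$col_map$b, c(1L, 3L, 4L))

  single <- as_reference_msa(c(only = "ACGT"))
  expect_equal(single$N, 1L)

  expect_error(as_reference_msa(c(a = "ACGT", b = "ACGTA")), "not an alignment")
  expect_error(as_reference_msa(c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(as_reference_msa(c(a = "ACXT")), "invalid symbol 'X'")
  expect_error(as_reference_msa(setNames("ACGT", "")), "nonempty")

  # lowercase and U normalize to uppercase T
  norm <- as_reference_msa(c(a = "acgu"))
  expect_equal(norm$seqs, "ACGT")
})

test_that("FASTA round trip preserves gapped rows", {
  msa <- tiny_msa()
  fa <- tempfile(fileext = ".fasta")
  write_fasta(setNames(msa$seqs, msa$names), fa)
  back <- read_reference_msa(fa)
  expect_equal(back$seqs, msa$seqs)
  expect_equal(back$names, msa$names)
})

test_that("read_airr enforces required columns and skips empty alignments", {
  dt <- airr_record(seq_aln = "ACGT", germ_aln = "ACGT")
  dt$extra_col <- "kept"
  p <- write_airr_tsv(dt)
  got <- read_airr(p)
  expect_equal(got$extra_col, "kept")
  expect_s3_class(got, "data.table")

  p2 <- write_airr_tsv(dt[, !"v_germline_start"])
  expect_error(read_airr(p2), "v_germline_start")

  dt3 <- rbind(dt, dt)
  dt3$sequence_id <- c("q1", "q2")
  dt3$v_sequence_alignment[2] <- ""
  p3 <- write_airr_tsv(dt3)
  expect_message(got3 <- read_airr(p3), "1 record")
  expect_equal(nrow(got3), 1L)
  expect_equal(attr(got3, "skipped_empty"), 1L)

  p4 <- write_airr_tsv(dt[0])
  expect_warning(got4 <- read_airr(p4), "no usable records")
  expect_equal(nrow(got4), 0L)
})

test_that("threading a reference onto itself reproduces the row", {
  msa <- tiny_msa()
  for (v in msa$names) {
    ungapped <- gsub("-", "", msa$seqs[msa$names == v])
    rec <- airr_record(v_call = v, seq_aln = ungapped, germ_aln = ungapped)
    tq <- thread_query(rec, msa)
    row <- strsplit(msa$seqs[msa$names == v], "")[[1]]
    expect_equal(tq$obs, row)
    expect_equal(tq$assigned_v, v)
  }
})

test_that("threading handles indels, partial coverage and odd symbols", {
  msa <- as_reference_msa(c(a = "ACGTAC", b = "AC--AC"))
  # query insertion relative to germline b: inserted base dropped, length still L
  rec <- airr_record(v_call = "b", seq_aln = "ACGAC", germ_aln = "AC-AC",
                     start = 1L)
  tq <- thread_query(rec, msa)
  expect_length(tq$obs, msa$L)
  expect_equal(tq$obs, c("A", "C", "-", "-", "A", "C"))

  # query deletion: '-' placed at that column (emission-neutral)
  rec2 <- airr_record(v_call = "a", seq_aln = "AC-TAC", germ_aln = "ACGTAC")
  expect_equal(thread_query(rec2, msa)$obs[3], "-")

  # partial coverage: uncovered columns stay '-'
  rec3 <- airr_record(v_call = "a", seq_aln = "GTA", germ_aln = "GTA",
                      start = 3L)
  expect_equal(thread_query(rec3, msa)$obs, c("-", "-", "G", "T", "A", "-"))

  # multi-allele v_call uses the first listed
  rec4 <- airr_record(v_call = "b, a", seq_aln = "ACAC", germ_aln = "ACAC")
  expect_equal(thread_query(rec4, msa)$assigned_v, "b")

  # symbols outside the alphabet become N
  rec5 <- airr_record(v_call = "a", seq_aln = "ACRTAC", germ_aln = "ACGTAC")
  expect_equal(thread_query(rec5, msa)$obs[3], "N")

  # germline walk beyond the reference is a malformed record
  rec6 <- airr_record(v_call = "b", seq_aln = "ACACA", germ_aln = "ACACA",
                      start = 1L)
  expect_error(thread_query(rec6, msa), "exceeds ungapped length")

  # unknown allele raises a typed condition; thread_queries skips or stops
  rec7 <- airr_record(v_call = "zz", seq_aln = "AC", germ_aln = "AC")
  expect_error(thread_query(rec7, msa), class = "vchimera_unknown_reference")
  both <- rbind(rec4, rec7)
  expect_message(th <- thread_queries(both, msa), "skipped")
  expect_equal(th$kept, 1L)
  expect_equal(th$n_skipped_unknown, 1L)
  expect_error(thread_queries(both, msa, strict = TRUE),
               class = "vchimera_unknown_reference")
})

test_that("detect output appends call columns and round-trips input cells", {
  records <- data.table::data.table(
    sequence_id = c("q1", "q2", "q3"),
    v_call = c("a", "b", "a"),
    v_sequence_alignment = c("ACGT", "AGT", "ACGT"),
    v_germline_alignment = c("ACGT", "AGT", "ACGT"),
    v_germline_start = c("1", "1", "1"),
    v_germline_end = c("4", "3", "4"),
    note = c("x y", "0.10", ""))
  calls <- data.frame(posterior = c(0.97, 0.95, 1.2e-8),
                      chimera = c(TRUE, TRUE, FALSE))
  p <- tempfile(fileext = ".tsv")
  write_detect_output(records, calls, p)
  back <- data.table::fread(p, sep = "\t", colClasses = "character",
                            na.strings = NULL)
  expect_equal(ncol(back), ncol(records) + 2L)
  for (cn in names(records))
    expect_identical(back[[cn]], records[[cn]])
  # call rule is >=: 0.95 at threshold 0.95 is a chimera
  expect_equal(back$chimera, c("T", "T", "F"))
  # >= 6 significant digits, plain decimal
  expect_match(back$chimera_probability[3], "^0\\.0+12")
  expect_error(write_detect_output(records, calls[1:2, ], p),
               "differ in length")
})
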