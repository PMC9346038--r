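test_that("global alignment percentages behave on elementary cases", {
  s <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  self <- global_align(s, s)
  expect_equal(self$percent_identity, 100)
  expect_equal(self$percent_similarity, 100)

  r <- global_align("ACD", "ACE")
  expect_equal(r$percent_identity, 100 * 2 / 3, tolerance = 1e-12)
  expect_gte(r$percent_similarity, r$percent_identity)
  expect_equal(nchar(r$aligned_query), nchar(r$aligned_reference))
  expect_equal(gsub("-", "", r$aligned_query), "ACD")
  expect_equal(gsub("-", "", r$aligned_reference), "ACE")
})

test_that("alignment scores match the exhaustive enumeration oracle", {
  set.seed(7)
  sc <- align_scoring()
  for (k in 1:12) {
    a <- random_protein(sample(3:6, 1))
    b <- random_protein(sample(3:6, 1))
    got <- global_align(a, b, sc)$score
    want <- oracle_align_score(a, b, sc$matrix, sc$gap_open, sc$gap_extend)
    expect_equal(got, want, tolerance = 1e-9,
                 label = sprintf("score(%s, %s)", a, b))
  }
})

test_that("identity and similarity are symmetric for homologous pairs", {
  set.seed(11)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- random_protein(40)
  for (k in 1:8) {
    mut <- function() {
      r <- strsplit(base, "")[[1]]
      idx <- sample(40, 8)
      r[idx] <- sample(aas, 8, TRUE)
      if (k %% 2 == 0) r <- r[-sample(40, 2)]  # occasional indels
      paste(r, collapse = "")
    }
    a <- mut(); b <- mut()
    ab <- global_align(a, b)
    ba <- global_align(b, a)
    expect_equal(ab$score, ba$score, tolerance = 1e-9)
    expect_equal(ab$percent_identity, ba$percent_identity, tolerance = 1e-9)
    expect_equal(ab$percent_similarity, ba$percent_similarity, tolerance = 1e-9)
  }
})

test_that("alignment inputs are validated", {
  expect_error(global_align("", "ACD"), "empty")
  expect_error(global_align("ACB", "ACD"), "B")
  expect_error(protein_record("t", "MKL", source_cds = "ATGAAA"),
               "length")
})

test_that("X scores zero and never counts as identical", {
  r <- global_align("AXA", "AXA")
  # 2 of 3 columns identical (the X pair is excluded)
  expect_equal(r$percent_identity, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(r$percent_similarity, 100 * 2 / 3, tolerance = 1e-12)
})

test_that("inclusion filter applies >=50 identity and >=60 similarity, identity first", {
  drafts <- data.frame(
    taxon = c("a", "b", "c", "d"),
    identity = c(50.0, 49.9, 80.0, 75.0),
    similarity = c(60.0, 95.0, 59.0, 80.0))
  out <- apply_inclusion_filter(drafts)
  expect_equal(out$included, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$exclusion_reason,
               c("none", "below_identity", "below_similarity", "none"))
  # included <=> reason none
  expect_equal(out$included, out$exclusion_reason == "none")
  # idempotent and order-independent
  expect_equal(apply_inclusion_filter(out), out)
  perm <- c(3, 1, 4, 2)
  out2 <- apply_inclusion_filter(drafts[perm, ])
  expect_equal(out2$included, out$included[perm])
  expect_error(apply_inclusion_filter(drafts, identity_min = -5), "non-negative")
})

test_that("canonical-start trimming removes upstream extensions only", {
  ref <- protein_record("ref", paste0("M", random_protein(49)))
  # constructed 20-residue extension ahead of an exact copy
  set.seed(3)
  ext <- random_protein(20)
  q <- protein_record("q", paste0(ext, ref$sequence))
  tr <- trim_to_canonical_start(q, ref)
  expect_equal(tr$trimmed_offset, 20L)
  expect_equal(tr$record$sequence, ref$sequence)

  # already canonical: no-op
  tr0 <- trim_to_canonical_start(ref, ref)
  expect_equal(tr0$trimmed_offset, 0L)
  # trimming is a no-op on its own output
  tr2 <- trim_to_canonical_start(tr$record, ref)
  expect_equal(tr2$trimmed_offset, 0L)
  expect_equal(tr2$record$sequence, tr$record$sequence)
})

test_that("trimming matches the oracle alignment for a mutated extension", {
  set.seed(5)
  base <- paste0("M", random_protein(11))
  q_res <- strsplit(base, "")[[1]]
  q_res[c(4, 7, 10)] <- c("W", "W", "W")  # internal substitutions
  q <- paste0("GGGGGGG", paste(q_res, collapse = ""))  # 7-residue extension
  tr <- trim_to_canonical_start(q, base)
  expect_equal(tr$trimmed_offset, 7L)
  expect_equal(nchar(tr$record$sequence), 12L)
  # CDS trimmed in register
  cds <- felscan:::.reverse_translate(q)
  q_rec <- protein_record("q", q, cds)
  tr_cds <- trim_to_canonical_start(q_rec, base)
  expect_equal(nchar(tr_cds$record$source_cds), 3 * 12 + 3)
})

test_that("ortholog assignment follows tree clustering", {
  set.seed(9)
  fam_a <- random_protein(40)
  fam_b <- random_protein(40)
  mk <- function(seq, fam, taxon, nmut = 3) {
    r <- strsplit(seq, "")[[1]]
    idx <- sample(seq_along(r), nmut)
    r[idx] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], nmut, TRUE)
    rec <- protein_record(taxon, paste(r, collapse = ""))
    attr(rec, "family") <- fam
    rec
  }
  panel <- c(lapply(1:3, function(i) mk(fam_a, "HspB1", paste0("a", i))),
             lapply(1:3, function(i) mk(fam_b, "HspB8", paste0("b", i))))
  # near-identical to an HspB1 member
  expect_equal(assign_ortholog_group(fam_a, panel), "HspB1")
  expect_equal(assign_ortholog_group(fam_b, panel), "HspB8")
  expect_error(assign_ortholog_group("M", panel[1:1]), "family labels|3 sequences")
})

test_that("curation pipeline composes filtering, trimming and reporting", {
  set.seed(21)
  ref <- protein_record("human", paste0("M", random_protein(59)))
  good <- protein_record("good", ref$sequence)
  resid <- strsplit(ref$sequence, "")[[1]]
  resid[-1] <- replace(resid[-1], sample(59, 40),
                       sample(c("G", "P", "W"), 40, TRUE))
  bad <- protein_record("bad", paste(resid, collapse = ""))
  cur <- curate_sequences(list(good, bad), ref)
  expect_equal(cur$report$taxon, c("good", "bad"))
  expect_true(cur$report$included[1])
  expect_false(cur$report$included[2])
  expect_equal(names(cur$records), "good")
  tmp <- tempfile(fileext = ".tsv")
  write_curation_report(cur$report, tmp)
  back <- read.delim(tmp)
  expect_equal(back$taxon, cur$report$taxon)
  expect_equal(back$included, cur$report$included)
})

test_that("reference column map drops reference-gap columns and inverts", {
  seqs <- c(ref = "ATG---AAACCC", other = "ATGGGGAAA---")
  aln <- codon_alignment(seqs, "ref")
  map <- map_alignment_to_reference(aln)
  expect_equal(map$reference_length, 3L)
  expect_equal(map$column_to_ref, c(1L, NA, 2L, 3L))
  # composed with its inverse: identity on mapped columns
  expect_equal(map$column_to_ref[map$ref_to_column],
               seq_len(map$reference_length))
  # strictly increasing over mapped columns
  expect_true(all(diff(stats::na.omit(map$column_to_ref)) > 0))

  solo <- codon_alignment(c(ref = "ATGAAACCC"), "ref")
  expect_equal(map_alignment_to_reference(solo)$reference_length, 3L)
  allgap <- codon_alignment(c(ref = "---", x = "ATG"), "ref")
  expect_error(map_alignment_to_reference(allgap), "all gaps")
})
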