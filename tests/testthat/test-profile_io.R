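# PSSM / structural-profile / label parsing, min-max normalization and
# file round-trips.

make_pssm_text <- function(rows, residues = NULL) {
  aa <- aa_alphabet()
  if (is.null(residues)) residues <- rep("A", length(rows))
  c("",
    "Last position-specific scoring matrix computed, weighted, observed percentages",
    paste0("            ", paste(sprintf("%3s", c(aa, aa)), collapse = "")),
    vapply(seq_along(rows), function(i) {
      paste0(sprintf("%5d %s ", i, residues[[i]]),
             paste(sprintf("%3d", rows[[i]]), collapse = ""),
             " ", paste(rep("  0", 20), collapse = ""),
             "  0.00      0.00")
    }, character(1)),
    "", "                      K         Lambda")
}

test_that("read_pssm parses a well-formed file and keeps the log-odds block", {
  rows <- list(c(5L, rep(0L, 19)), rep(1L, 20), c(rep(-2L, 19), 9L))
  p <- read_pssm(text = make_pssm_text(rows, c("A", "C", "V")))
  expect_s3_class(p, "evo_profile")
  expect_equal(dim(p$matrix), c(3L, 20L))
  expect_equal(p$sequence, "ACV")
  expect_equal(unname(p$matrix[1, ]), c(5, rep(0, 19)))
  expect_false(p$normalized)
})

test_that("malformed and empty PSSM input raise parse errors naming the line", {
  rows <- list(rep(0L, 20), rep(0L, 20))
  txt <- make_pssm_text(rows)
  # row 2 of the matrix sits at line 5; drop one score column from it
  txt[5] <- sub("  0 ", " ", txt[5])
  expect_error(read_pssm(text = txt), "line 5")
  expect_error(read_pssm(text = character(0)), "empty")
  expect_error(read_pssm(text = c("", "   ")), "empty")
})

test_that("min-max normalization maps extremes to 0 and 1", {
  m <- matrix(c(-3, 0, 2, 7), 2)
  nm <- normalize_min_max(m)
  expect_equal(min(nm), 0)
  expect_equal(max(nm), 1)
  expect_equal(nm[1, 1], 0)   # the -3 entry
  expect_equal(nm[2, 2], 1)   # the 7 entry
  expect_equal(normalize_min_max(matrix(5, 3, 4)),
               matrix(0, 3, 4))
  expect_error(normalize_min_max(matrix(c(1, NA), 1)), "non-finite")
})

test_that("min-max normalization matches the elementwise formula and is idempotent", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      m <- matrix(sample(-10:10, 40, replace = TRUE), 2, 20)
      nm <- normalize_min_max(m)
      expect_equal(nm, (m - min(m)) / (max(m) - min(m)))
      if (max(m) > min(m)) expect_equal(normalize_min_max(nm), nm)
    }
  })
})

test_that("structural profile parsing takes the file's state calls as consensus", {
  txt <- c("#  header",
           "1  A  H  0.90  0.05  0.05",
           "2  R  C  0.10  0.10  0.80")
  p <- read_structural_profile(text = txt)
  expect_equal(p$consensus, "HC")
  expect_equal(dim(p$matrix), c(2L, 3L))
  expect_equal(unname(p$matrix[2, ]), c(0.1, 0.1, 0.8))

  # the stated state wins even where it disagrees with the row argmax
  disagree <- read_structural_profile(
    text = "1 A E 0.90 0.05 0.05")
  expect_equal(disagree$consensus, "E")
})

test_that("structural profile parsing rejects bad states and probabilities", {
  expect_error(read_structural_profile(text = "1 A X 0.5 0.3 0.2"),
               "unknown secondary-structure state")
  expect_error(read_structural_profile(text = "1 A H 1.5 0.0 0.0"),
               "outside \\[0, 1\\]")
  expect_error(read_structural_profile(text = "1 A H 0.5"), "malformed")
  expect_error(read_structural_profile(text = "# only comments"),
               "no residue rows")
})

test_that("label tables normalize synonyms and reject unknown classes", {
  lab <- read_labels(text = c("p1,all-alpha", "p2,b", "p3,α/β", "p4,a+b"))
  expect_equal(nrow(lab), 4L)
  expect_setequal(lab$class, structural_classes())
  expect_equal(lab$class[lab$protein_id == "p1"], "all-alpha")
  expect_error(read_labels(text = "p1,gamma"), "accepted names")
  # tab-separated with a header line
  lab2 <- read_labels(text = c("protein_id\tclass", "x\tall-beta"))
  expect_equal(lab2$class, "all-beta")
})

test_that("FASTA sequences round-trip through the reader", {
  txt <- c(">p1 some description", "ACDEF", "GHIK", ">p2", "MNPQ")
  fa <- read_fasta_sequences(text = txt)
  expect_equal(fa$protein_id, c("p1", "p2"))
  expect_equal(fa$sequence, c("ACDEFGHIK", "MNPQ"))
})

test_that("synthetic profiles survive a write/read round-trip exactly", {
  withr::with_seed(11, {
    p <- generate_protein("alpha/beta", 60, noise = 0.5, protein_id = "rt")
  })
  dir <- withr::local_tempdir()
  pssm_path <- file.path(dir, "rt.pssm")
  ss_path <- file.path(dir, "rt.ss")
  write_pssm(p$evo_raw, pssm_path, percentages = p$percentages)
  write_structural_profile(p$struct, ss_path)

  back <- read_pssm(pssm_path, protein_id = "rt")
  expect_equal(back$matrix, p$evo_raw$matrix)
  expect_equal(back$sequence, p$evo_raw$sequence)

  sback <- read_structural_profile(ss_path, protein_id = "rt")
  expect_equal(sback$matrix, p$struct$matrix)
  expect_equal(sback$consensus, p$struct$consensus)
})

test_that("parsers never silently truncate: parsed L equals residue rows", {
  withr::with_seed(3, {
    for (L in c(1, 7, 33)) {
      p <- generate_protein("all-beta", L, noise = 0.4)
      dir <- withr::local_tempdir()
      write_pssm(p$evo_raw, file.path(dir, "x.pssm"))
      write_structural_profile(p$struct, file.path(dir, "x.ss"))
      expect_equal(nrow(read_pssm(file.path(dir, "x.pssm"))$matrix), L)
      expect_equal(nrow(read_structural_profile(
        file.path(dir, "x.ss"))$matrix), L)
    }
  })
})

test_that("feature tables round-trip through the delimited format", {
  ds <- generate_dataset(n_per_class = 1, length_range = c(20, 30),
                         noise = 0.2, seed = 9)
  feats <- extract_dataset(ds, scheme = "spine-s")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(feats, path)
  back <- read_feature_table(path)
  expect_equal(names(back), names(feats))
  expect_equal(as.data.frame(back), as.data.frame(feats), tolerance = 1e-12)
})
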