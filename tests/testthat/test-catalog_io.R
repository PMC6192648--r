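test_that("sequence normalization uppercases, strips one trailing stop, and is idempotent", {
  expect_identical(normalize_aa("mkv*"), "MKV")
  expect_identical(normalize_aa("MKV"), "MKV")
  expect_identical(normalize_aa(normalize_aa("mKv*")), normalize_aa("mKv*"))
  expect_error(normalize_aa("MK*V"), "internal stop")
  expect_error(normalize_aa("MKV1"), "non-IUPAC")
  expect_error(normalize_aa("*"), "empty")
})

test_that("family catalog reading joins FASTA and membership and validates ids", {
  members <- make_members(c("MKVLA", "MKTLA", "mkplA*"))
  files <- write_catalog_files(members)
  cat <- read_family_catalog(files$fasta, files$tsv)
  expect_s3_class(cat, "family_catalog")
  expect_equal(nrow(cat), 3L)
  expect_identical(cat$aa_seq[cat$seq_id == "FAM1_m03"], "MKPLA")
  expect_true(all(cat$has_start))
  expect_identical(length(split_families(cat)), 1L)

  # FASTA id missing from the TSV is named in the error
  writeLines(c(readLines(files$fasta), ">s9", "MMM"), files$fasta)
  expect_error(read_family_catalog(files$fasta, files$tsv), "s9")
})

test_that("membership rows without FASTA records and duplicate ids are rejected", {
  members <- make_members(c("MKVLA", "MKTLA"))
  files <- write_catalog_files(members)
  memb <- read.delim(files$tsv)
  memb <- rbind(memb, data.frame(seq_id = "ghost", family_id = "FAM1",
                                 taxon_id = "T01", has_start = 1,
                                 has_stop = 1))
  write.table(memb, files$tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_family_catalog(files$fasta, files$tsv), "ghost")

  memb <- memb[c(1, 1, 2), ]
  write.table(memb, files$tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_family_catalog(files$fasta, files$tsv), "duplicate")
})

test_that("catalog families are returned in lexicographic family order", {
  members <- rbind(make_members(c("MKV", "MKT", "MKA"), family_id = "FB"),
                   make_members(c("MLV", "MLT"), family_id = "FA"))
  files <- write_catalog_files(members)
  cat <- read_family_catalog(files$fasta, files$tsv)
  expect_identical(unique(cat$family_id), c("FA", "FB"))
  expect_identical(names(split_families(cat)), c("FA", "FB"))
})

test_that("lineage table reading nulls blank cells and rejects bad schemas", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "lin.tsv")
  lin <- make_lineage(c("T01", "T02"))
  lin$class[2] <- ""
  write.table(lin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_lineage_table(path)
  expect_identical(names(got), c("taxon_id", RANKS))
  expect_false(anyNA(got[got$taxon_id == "T01", RANKS]))
  expect_true(is.na(got$class[got$taxon_id == "T02"]))

  write.table(rbind(lin, lin[1, ]), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_lineage_table(path), "duplicate taxon_id")

  lin$strain <- "x"
  write.table(lin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_lineage_table(path), "unknown rank")
})

test_that("m8 parsing keeps file order, ignores extra columns, rejects bad rows", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "x.m8")
  row12 <- paste("r1", "p1", "99.5", "100", "0", "0", "1", "100", "1", "100",
                 "1e-20", "80.0", sep = "\t")
  row13 <- paste("r2", "p2", "98.0", "90", "2", "0", "1", "90", "1", "90",
                 "1e-10", "60.0", "extra", sep = "\t")
  writeLines(c(row12, row13), path)
  hits <- read_m8(path)
  expect_equal(nrow(hits), 2L)
  expect_identical(hits$read_id, c("r1", "r2"))
  expect_equal(hits[1, c("pct_identity", "align_len", "evalue", "bit_score")],
               data.frame(pct_identity = 99.5, align_len = 100L,
                          evalue = 1e-20, bit_score = 80.0),
               ignore_attr = TRUE)

  writeLines(c(row12, sub("98.0", "NA", row13)), path)
  expect_error(read_m8(path), "line 2")

  # N well-formed rows give exactly N hits in order
  n <- 25L
  rows <- vapply(seq_len(n), function(i) {
    paste(sprintf("r%03d", i), "p1", "99.0", "100", "0", "0", "1", "100",
          "1", "100", "1e-5", sprintf("%.1f", 50 + i), sep = "\t")
  }, character(1))
  writeLines(rows, path)
  got <- read_m8(path)
  expect_equal(nrow(got), n)
  expect_identical(got$read_id, sprintf("r%03d", seq_len(n)))
})

test_that("catalog report round-trips through TSV", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "report.tsv")
  report <- data.frame(
    family_id = sprintf("F%02d", 1:5), n_members = 3:7, n_unique = 3:7,
    pass_filter = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    annotated = c(FALSE, TRUE, FALSE, FALSE, TRUE),
    n_species = 5:1, n_genera = 5:1, n_families = 5:1, n_orders = 5:1,
    n_classes = c(3L, 2L, 1L, 2L, 1L), n_phyla = c(2L, 2L, 1L, 1L, 1L),
    n_kingdoms = 1L, n_domains = 1L,
    is_funkfam = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  write_catalog_report(report, path)
  expect_identical(read_catalog_report(path), report)

  write_catalog_report(report[0, ], path)
  expect_equal(length(readLines(path)), 1L)  # header only

  expect_error(write_catalog_report(report[, -which(names(report) == "n_phyla")],
                                    path), "n_phyla")
})

test_that("sample metadata validation enforces positive depth and read length", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "md.tsv")
  md <- data.frame(sample_id = c("s1", "s2"), environment = "ENV_A",
                   read_length = c(100L, 100L),
                   genome_equivalents = c(10, 20), stratum = "ENV_A",
                   group = c("X", "Y"))
  write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_sample_metadata(path)
  expect_identical(got$sample_id, c("s1", "s2"))
  expect_identical(got$group, c("X", "Y"))

  md$genome_equivalents[1] <- 0
  write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_metadata(path), "genome_equivalents")
})
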