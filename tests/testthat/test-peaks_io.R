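# BED reading in the ReMap name dialect, CRM filtering, peak assignment and
# scored-BED writing.

write_bed_fixture <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

test_that("ReMap name fields map to dataset/regulator/cell line with exact-match filtering", {
  path <- write_bed_fixture(c(
    "chr1\t100\t600\tGSE52924.BRD4.HELA\t0\t.",
    "chr1\t700\t900\tGSE11111.CTCF.HELA\t0\t.",
    "chr1\t950\t1000\tGSE11111.BRD4.K562\t0\t."))
  rd <- read_remap_bed(path, "HELA")
  expect_equal(nrow(rd$peaks), 2)
  expect_equal(rd$peaks$chrom[1], "chr1")
  expect_equal(rd$peaks$start[1], 100)
  expect_equal(rd$peaks$end[1], 600)
  expect_equal(rd$peaks$dataset, c("GSE52924", "GSE11111"))
  expect_equal(rd$peaks$regulator, c("BRD4", "CTCF"))
  expect_equal(rd$peaks$cell_line, c("HELA", "HELA"))
  # filtering on an absent cell line empties the catalogue -> error
  expect_error(read_remap_bed(path, "CD34"), "no peaks")
  # extra dot-tokens are appended to the dataset
  p2 <- write_bed_fixture("chr2\t1\t50\tGSE1.sub2.MYC.HELA\t0\t.")
  rd2 <- read_remap_bed(p2, "HELA")
  expect_equal(rd2$peaks$dataset, "GSE1.sub2")
  expect_equal(rd2$peaks$regulator, "MYC")
})

test_that("malformed name fields are skipped with a warning, or abort in strict mode", {
  path <- write_bed_fixture(c(
    "chr1\t10\t20\tbadname\t0\t.",
    "chr1\t30\t40\tGSE1.TF1.HELA\t0\t."))
  expect_warning(rd <- read_remap_bed(path, "HELA"), "line")
  expect_equal(nrow(rd$peaks), 1)
  expect_equal(rd$peaks$line_index, 2L)
  expect_error(suppressWarnings(read_remap_bed(path, "HELA", strict = TRUE)),
               "unparsable")
})

test_that("catalog axes are deterministic and abundances count peaks", {
  path <- write_bed_fixture(c(
    "chr1\t10\t20\tGSEB.TF2.H\t0\t.",
    "chr1\t30\t40\tGSEA.TF1.H\t0\t.",
    "chr1\t50\t60\tGSEA.TF1.H\t0\t."))
  rd <- read_remap_bed(path, "H")
  expect_equal(rd$catalog$datasets, c("GSEA", "GSEB"))   # lexicographic
  expect_equal(rd$catalog$regulators, c("TF1", "TF2"))
  expect_equal(dim(rd$catalog$abundance), c(2L, 2L))
  expect_equal(rd$catalog$abundance["GSEA", "TF1"], 2L)
  expect_equal(rd$catalog$abundance["GSEB", "TF2"], 1L)
  expect_equal(sum(rd$catalog$abundance), 3L)
  # two sources, 2x2 catalog as counted on the fixture
  expect_equal(unname(rd$catalog$abundance["GSEA", "TF2"]), 0L)
})

test_that("filter_crms applies the peak-count threshold and keeps order", {
  regions <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                        end = c(50, 150, 250), crm_id = 1:3,
                        peak_count = c(99L, 100L, 101L))
  expect_equal(filter_crms(regions, 100)$crm_id, 2:3)
  expect_equal(filter_crms(regions, 0), regions)
  # brute-force agreement on a random fixture
  set.seed(1)
  counts <- sample.int(200, 20)
  rg <- data.frame(chrom = "chr1", start = seq(0, by = 100, length.out = 20),
                   end = seq(50, by = 100, length.out = 20), crm_id = 1:20,
                   peak_count = counts)
  thr <- stats::median(counts)
  expect_equal(filter_crms(rg, thr)$crm_id, rg$crm_id[counts >= thr])
  rg$peak_count[3] <- NA
  expect_error(filter_crms(rg, 10), "peak_count")
})

test_that("assign_peaks uses half-open overlap and matches a brute-force oracle", {
  peaks <- data.frame(chrom = "chr1", start = c(100, 100), end = c(200, 150),
                      dataset = "D", regulator = "T")
  regions <- data.frame(chrom = "chr1", start = 150, end = 400, crm_id = 7L)
  asg <- assign_peaks(peaks, regions)
  expect_equal(asg$assigned[["7"]], 1L)        # [100,200) overlaps [150,400)
  expect_equal(asg$unassigned, 2L)             # [100,150) does not (half-open)

  set.seed(42)
  n <- 50
  st <- sort(sample.int(5000, n))
  pk <- data.frame(chrom = "chr1", start = st,
                   end = st + sample.int(400, n), dataset = "D",
                   regulator = "T")
  rg <- data.frame(chrom = "chr1", start = seq(0, 4000, by = 1000),
                   end = seq(0, 4000, by = 1000) + 600, crm_id = 1:5)
  asg <- assign_peaks(pk, rg)
  # quadratic oracle
  for (i in seq_len(nrow(rg))) {
    ov <- which(pk$start < rg$end[i] & pk$end > rg$start[i])
    got <- asg$assigned[[as.character(rg$crm_id[i])]]
    expect_equal(sort(if (is.null(got)) integer(0) else got), ov)
  }
  oracle_un <- which(!sapply(seq_len(n), function(j)
    any(pk$start[j] < rg$end & pk$end[j] > rg$start)))
  expect_equal(sort(asg$unassigned), oracle_un)

  expect_error(assign_peaks(pk[c(2, 1), ], rg), "sorted")
})

test_that("scored BED output clamps and rounds the score field, keeping the raw value", {
  peaks <- data.frame(chrom = "chr1", start = c(0, 10, 20),
                      end = c(5, 15, 25),
                      name = c("A.T.H", "B.T.H", "C.T.H"), strand = ".")
  path <- tempfile(fileext = ".bed")
  write_scored_bed(peaks, c(750.0, 1340.2, -12), path)
  out <- utils::read.table(path, sep = "\t")
  expect_equal(out$V5, c(750L, 1000L, 0L))
  expect_equal(out$V7, c(750.0, 1340.2, -12))
  expect_error(write_scored_bed(peaks, c(1, NA, 3), path), "score")
  expect_error(write_scored_bed(peaks, c(1, 2), path), "score")
})

test_that("read -> write round trip preserves coordinates, names and strands", {
  lines <- c("chr1\t100\t600\tGSE52924.BRD4.HELA\t0\t+",
             "chr2\t5\t99\tGSE1.CTCF.HELA\t0\t-")
  path <- write_bed_fixture(lines)
  rd <- read_remap_bed(path, "HELA")
  out <- tempfile(fileext = ".bed")
  write_scored_bed(rd$peaks, c(1, 2), out)
  wrote <- utils::read.table(out, sep = "\t", colClasses = "character")
  orig <- utils::read.table(path, sep = "\t", colClasses = "character")
  expect_identical(wrote[, c(1:4, 6)], orig[, c(1:4, 6)])
})

test_that("crm_peak_counts counts boundary-spanning peaks in both regions", {
  peaks <- data.frame(chrom = "chr1", start = c(50, 950, 1500),
                      end = c(80, 1050, 1600), dataset = "D", regulator = "T")
  regions <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000),
                        crm_id = 1:2)
  out <- crm_peak_counts(peaks, regions)
  expect_equal(out$peak_count, c(2L, 2L))  # middle peak counted in both
})
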