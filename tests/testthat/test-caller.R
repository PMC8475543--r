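panel <- builtin_assays()

test_that("Cq tables read the NF-as-zero convention in both layouts", {
  wide <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,assay,replicate,fam_cq,vic_cq",
               "S1,SNP A,1,23.1,0",
               "S1,SNP A,2,23.3,",
               "S2,SNP B,1,24.0,25.5"), wide)
  rec <- read_cq_table(wide)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$fam_cq[1], 23.1)
  expect_true(is.na(rec$vic_cq[1]))    # 0 -> NF
  expect_true(is.na(rec$vic_cq[2]))    # blank -> NF

  long <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,assay,replicate,fluorophore,cq",
               "S1,SNP A,1,FAM,23.1", "S1,SNP A,1,VIC,0",
               "S1,SNP A,2,FAM,23.3", "S1,SNP A,2,VIC,24.8"), long)
  rl <- read_cq_table(long)
  expect_equal(nrow(rl), 2L)
  expect_equal(rl$fam_cq, c(23.1, 23.3))
  expect_true(is.na(rl$vic_cq[1]))
  expect_equal(rl$vic_cq[2], 24.8)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample,assay,replicate,fam_cq,vic_cq", empty)
  expect_equal(nrow(read_cq_table(empty)), 0L)
})

test_that("malformed Cq tables raise classed errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,assay,fam_cq,vic_cq", "S1,SNP A,23,24"), p)
  expect_error(read_cq_table(p), class = "fawstrain_format_error")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,assay,replicate,fam_cq,vic_cq",
               "S1,SNP A,1,45,24"), p2)
  expect_error(read_cq_table(p2), class = "fawstrain_value_error")

  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,assay,replicate,fam_cq,vic_cq",
               "S1,SNP A,1,-1,24"), p3)
  expect_error(read_cq_table(p3), class = "fawstrain_value_error")
})

test_that("cq tables round-trip through write_cq_table", {
  rec <- cq_records("S1", "SNP A", fam = c(23.0, 23.2), vic = c(NA, NA))
  p <- withr::local_tempfile(fileext = ".csv")
  write_cq_table(rec, p)
  back <- read_cq_table(p)
  expect_equal(back$fam_cq, rec$fam_cq)
  expect_true(all(is.na(back$vic_cq)))
})

test_that("replicate aggregation applies the all-replicates NF rule", {
  rec <- rbind(
    cq_records("S1", "SNP A", fam = c(23.0, 23.2), vic = c(24.0, NA)),
    cq_records("S2", "SNP A", fam = 22.5, vic = 24.5))
  agg <- aggregate_replicates(rec)
  s1 <- agg[agg$sample_id == "S1", ]
  expect_equal(s1$fam_cq_mean, 23.1)
  expect_true(s1$fam_detected)
  expect_false(s1$vic_detected)        # NF in one replicate -> not detected
  expect_true(is.na(s1$vic_cq_mean))
  s2 <- agg[agg$sample_id == "S2", ]
  expect_equal(s2$n_replicates, 1L)
  expect_equal(s2$fam_cq_mean, 22.5)
})

test_that("deltaCq is non-negative with the earlier fluorophore leading", {
  agg <- aggregate_replicates(rbind(
    cq_records("A", "SNP B", fam = c(23.0, 23.0), vic = c(39.3, 39.3)),
    cq_records("B", "SNP B", fam = c(23.9, 23.9), vic = c(23.1, 23.1)),
    cq_records("C", "SNP A", fam = c(23.0, 23.0), vic = c(NA, NA))))
  d <- delta_cq(agg)
  d <- d[order(d$sample_id), ]
  expect_equal(d$delta_cq[1], 16.3)
  expect_equal(d$leading_fluorophore[1], "FAM")
  expect_equal(d$delta_cq[2], 0.8)
  expect_equal(d$leading_fluorophore[2], "VIC")
  expect_true(is.na(d$delta_cq[3]))
  expect_equal(d$flags[3], "SINGLE_FLUOROPHORE")
  expect_true(all(d$delta_cq >= 0, na.rm = TRUE))
})

test_that("genotype calling follows the deltaCq rules", {
  call1 <- function(fam, vic, assay = "SNP A") {
    agg <- aggregate_replicates(cq_records("S", assay, fam, vic))
    call_genotype(agg, panel[[assay]])
  }
  expect_equal(call1(c(23.1, 23.1), c(NA, NA))$call, "RR")   # FAM only
  expect_equal(call1(c(NA, NA), c(23.1, 23.1))$call, "CC")   # VIC only
  expect_equal(call1(c(23.5, 23.5), c(23.9, 23.9))$call, "H")
  b <- call1(c(39.0, 39.0), c(23.0, 23.0), "SNP B")
  expect_equal(b$call, "CC")
  expect_equal(b$delta_cq, 16.0)
  expect_equal(call1(c(25.5, 25.5), c(23.0, 23.0))$call, "INCONCLUSIVE")
  nosig <- call1(c(NA, NA), c(NA, NA))
  expect_equal(nosig$call, "INCONCLUSIVE")
  expect_match(nosig$flags, "NO_SIGNAL")
  low <- call1(c(31.0, 31.0), c(NA, NA))
  expect_equal(low$call, "RR")
  expect_match(low$flags, "LOW_TEMPLATE")
  expect_error(call_genotype(aggregate_replicates(
    cq_records("S", "COI", 23, 24)), panel[["COI"]]),
    class = "fawstrain_usage_error")
})

test_that("swapping FAM and VIC flips RR and CC, preserves H/INCONCLUSIVE", {
  set.seed(41)
  for (i in 1:25) {
    fam <- round(runif(2, 20, 33), 2)
    vic <- pmin(fam + sample(c(-1, 1), 1) * runif(2, 0, 12), 40)
    if (runif(1) < 0.2) vic <- c(NA, NA)
    agg <- aggregate_replicates(cq_records("S", "SNP B", fam, vic))
    swapped <- aggregate_replicates(cq_records("S", "SNP B", vic, fam))
    a <- call_genotype(agg, panel[["SNP B"]])$call
    b <- call_genotype(swapped, panel[["SNP B"]])$call
    expected <- c(RR = "CC", CC = "RR", H = "H",
                  INCONCLUSIVE = "INCONCLUSIVE")[[a]]
    expect_equal(b, expected)
  }
})

test_that("deltaCq is invariant to a constant Cq shift", {
  agg <- aggregate_replicates(cq_records("S", "SNP B", c(23, 23.2),
                                         c(27.5, 27.7)))
  shifted <- aggregate_replicates(cq_records("S", "SNP B", c(26, 26.2),
                                             c(30.5, 30.7)))
  expect_equal(delta_cq(agg)$delta_cq, delta_cq(shifted)$delta_cq)
})

test_that("raising the off-target Cq never turns a homozygote into a het", {
  # borderline homozygote: delta exactly at homo_min_delta
  for (extra in c(0, 0.5, 2, 8)) {
    agg <- aggregate_replicates(
      cq_records("S", "SNP B", c(23, 23), c(26, 26) + extra))
    call <- call_genotype(agg, panel[["SNP B"]])$call
    expect_equal(call, "RR")
  }
})

test_that("call_plate calls every sample x assay deterministically", {
  rec <- rbind(
    cq_records("S2", "SNP B", c(23, 23.1), c(39, 39.2)),
    cq_records("S1", "SNP A", c(23, 23.1), c(NA, NA)),
    cq_records("S1", "SNP B", c(23.4, 23.5), c(23.6, 23.4)),
    cq_records("S2", "SNP A", c(NA, NA), c(NA, NA)))
  calls <- call_plate(rec, panel)
  expect_equal(nrow(calls), 4L)
  expect_equal(calls$sample_id, c("S1", "S1", "S2", "S2"))
  expect_equal(calls$assay_id, c("SNP A", "SNP B", "SNP A", "SNP B"))
  expect_equal(calls$call, c("RR", "H", "INCONCLUSIVE", "RR"))
  expect_match(calls$flags[3], "NO_SIGNAL")
})

test_that("caller recovers simulated genotypes at high concordance", {
  profiles <- assay_sim_profiles()
  set.seed(99)
  truth <- expand.grid(sample_id = sprintf("S%04d", 1:90),
                       assay_id = profiles$assay_id,
                       stringsAsFactors = FALSE)
  truth$genotype <- rep(c("RR", "CC", "H"), length.out = nrow(truth))
  sim <- simulate_cq_dataset(truth, profiles, seed = 424)
  calls <- call_plate(sim$records, panel)
  merged <- merge(calls, truth, by = c("sample_id", "assay_id"))
  concordance <- mean(merged$call == merged$genotype)
  expect_gte(concordance, 0.99)
})
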