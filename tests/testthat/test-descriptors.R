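test_that("graph descriptors count nitrogens and carbon valency", {
  ethylenediamine <- moleculeGraph(c("N", "C", "C", "N"),
                                   data.frame(a1 = 1:3, a2 = 2:4, order = 1))
  d <- computeGraphDescriptors(ethylenediamine)
  expect_equal(unname(d["NN"]), 2)
  methane <- moleculeGraph("C")
  expect_equal(unname(computeGraphDescriptors(methane)["AVC"]), 4.0)
  # bis(2-chloroethyl)amine fragment N(CH2CH2Cl)2
  frag <- moleculeGraph(c("N", "C", "C", "Cl", "C", "C", "Cl"),
                        data.frame(a1 = c(1, 2, 3, 1, 5, 6),
                                   a2 = c(2, 3, 4, 5, 6, 7), order = 1))
  expect_equal(unname(computeGraphDescriptors(frag)["NN"]), 1)
  # no carbon: AVC is missing, not zero
  water <- moleculeGraph(c("O", "H", "H"),
                         data.frame(a1 = c(1, 1), a2 = c(2, 3), order = 1))
  expect_true(is.na(computeGraphDescriptors(water)["AVC"]))
})

test_that("SMILES parsing feeds the graph descriptors", {
  skip_if_not_installed("ChemmineR")
  d <- computeGraphDescriptors("NCCN")
  expect_equal(unname(d["NN"]), 2)
  expect_equal(unname(d["AVC"]), 4.0)
  expect_equal(unname(computeGraphDescriptors("ClCCN(CCCl)C")["NN"]), 1)
})

makeCS <- function(ids) {
  p <- writeTinyCompoundCSV(withr::local_tempfile(fileext = ".csv",
                                                  .local_envir = parent.frame()),
                            ids = ids, ic50 = seq_along(ids))
  readCompoundTable(p)
}

writeDescCSV <- function(values, env = parent.frame()) {
  p <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  df <- data.frame(compound_id = rownames(values), values,
                   check.names = FALSE)
  write.csv(df, p, row.names = FALSE, quote = FALSE)
  p
}

test_that("assembleDescriptors screens constant and missing columns", {
  cs <- makeCS(sprintf("C%02d", 1:22))
  set.seed(5)
  vals <- matrix(rnorm(22 * 50), 22, 50,
                 dimnames = list(compoundIds(cs), paste0("d", 1:50)))
  vals[, c(3, 17, 40)] <- 1.25  # three constant columns
  p <- writeDescCSV(vals)
  dm <- assembleDescriptors(cs, imported = p)
  expect_equal(ncol(dm), 47L)
  expect_false(any(c("d3", "d17", "d40") %in% descriptorNames(dm)))
  expect_equal(compoundIds(dm), compoundIds(cs))
  expect_length(dm@dropLog, 3L)
})

test_that("assembleDescriptors errors name the uncovered compound", {
  cs <- makeCS(c("I8", "I9", "I10", "I11"))
  vals <- matrix(rnorm(3 * 4), 3, 4,
                 dimnames = list(c("I8", "I10", "I11"), paste0("d", 1:4)))
  expect_error(assembleDescriptors(cs, imported = writeDescCSV(vals)), "I9")
})

test_that("screening is idempotent and order-deterministic", {
  cs <- makeCS(sprintf("C%d", 1:10))
  set.seed(9)
  vals <- matrix(rnorm(10 * 8), 10, 8,
                 dimnames = list(compoundIds(cs), paste0("d", 1:8)))
  vals[, 2] <- 0
  dm1 <- assembleDescriptors(cs, imported = writeDescCSV(vals))
  # re-assemble from the already screened matrix
  p2 <- writeDescCSV(descriptorValues(dm1))
  dm2 <- assembleDescriptors(cs, imported = p2)
  expect_identical(descriptorValues(dm2), descriptorValues(dm1))
  expect_length(dm2@dropLog, 0L)
})

test_that("partial per-compound value maps merge and NA columns drop", {
  cs <- makeCS(c("A", "B", "C"))
  vals <- matrix(1:6 + 0.5, 3, 2, dimnames = list(c("A", "B", "C"),
                                                  c("imp1", "imp2")))
  computed <- list(A = c(NN = 2, AVC = 4), B = c(NN = 1, AVC = 3.9),
                   C = c(NN = 0))  # AVC missing for C -> column dropped
  dm <- assembleDescriptors(cs, imported = writeDescCSV(vals),
                            computed = computed,
                            classes = c(NN = "constitutional"))
  expect_setequal(descriptorNames(dm), c("imp1", "imp2", "NN"))
  expect_true(any(grepl("AVC", dm@dropLog)))
  expect_equal(unname(descriptorClasses(dm)["NN"]), "constitutional")
  expect_equal(unname(descriptorClasses(dm)["imp1"]), "imported")
})
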