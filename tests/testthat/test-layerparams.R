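test_that("built-in material table carries the adopted values and trends", {
  tab <- builtin_table1()
  expect_named(tab, c("Epi", "PD", "RD", "Hypo", "Muscle"))
  expect_equal(tab$Epi$mu0, 0.508e-2)
  expect_equal(tab$RD$beta0, 2.49e-3)
  for (p in tab) {
    expect_equal(p$kappa, 2)
    expect_equal(p$beta1, 2)
    expect_equal(p$phi_s_ref, 0.3)
  }
  # inter-layer trends: fiber stiffness and permeability grow with depth,
  # the out-of-plane fiber angle shrinks
  expect_true(tab$RD$m_fe > tab$PD$m_fe && tab$PD$m_fe > tab$Epi$m_fe)
  expect_true(tab$Epi$k0 < tab$PD$k0 && tab$PD$k0 < tab$RD$k0)
  expect_true(tab$Epi$theta > tab$PD$theta && tab$PD$theta > tab$RD$theta)
  # muscle has no fiber phase at all
  expect_equal(tab$Muscle$m_fe, 0)
  expect_equal(tab$Muscle$m_fd, 0)
  expect_equal(tab$Muscle$theta, 0)
  expect_equal(tab$Muscle$k_fd, 0)
})

test_that("parameter validation rejects unphysical values", {
  p <- unclass(builtin_table1()$RD)
  expect_s3_class(do.call(layer_params, p), "LayerParams")
  for (bad in list(c("mu0", -1), c("thickness", 0), c("phi_s_ref", 1.2),
                   c("theta", 120), c("k0", -0.1))) {
    q <- p; q[[bad[1]]] <- as.numeric(bad[2])
    expect_error(do.call(layer_params, q), bad[1])
  }
  expect_error(do.call(layer_params, c(p, list(zzz = 1))), "unknown")
})

test_that("stacks assemble, validate and total their thickness", {
  st <- skin_stack(2)
  expect_equal(names(st$layers), c("Epi", "PD", "RD"))
  expect_equal(st$total_thickness, 2)
  expect_equal(st$layers$RD$thickness, 1.7)
  tab <- builtin_table1()
  expect_error(layer_stack(list(A = tab$Epi, A = tab$PD)), "unique")
})

test_that("YAML stack config round-trips exactly and validates", {
  f <- tempfile(fileext = ".yml")
  writeLines(c("layers:",
               "  - name: Epi", "    thickness: 0.1",
               "  - name: PD", "    thickness: 0.2",
               "  - name: RD", "    thickness: 1.7"), f)
  st <- load_stack(f)
  expect_equal(st$total_thickness, 2.0)
  # suction variant of the reticular dermis thickness
  writeLines(c("layers:",
               "  - name: Epi", "    thickness: 0.1",
               "  - name: PD", "    thickness: 0.2",
               "  - name: RD", "    thickness: 1.1"), f)
  expect_equal(load_stack(f)$total_thickness, 1.4)
  # invalid configs fail loudly
  writeLines(c("layers:",
               "  - name: Epi", "    thickness: 0"), f)
  expect_error(load_stack(f), "thickness")
  writeLines(c("layers:",
               "  - name: Epi", "    nonsense: 1"), f)
  expect_error(load_stack(f), "unknown key")
  # exact numeric round trip through write_stack
  st <- skin_stack(2)
  st$layers$RD$mu0 <- 1 / 3 * 1e-2
  g <- tempfile(fileext = ".yml")
  write_stack(st, g)
  st2 <- load_stack(g)
  for (nm in names(st$layers))
    expect_identical(unlist(unclass(st$layers[[nm]])),
                     unlist(unclass(st2$layers[[nm]])))
})

test_that("CSV export mirrors the table layout", {
  f <- tempfile(fileext = ".csv")
  df <- export_table1_csv(f)
  got <- utils::read.csv(f, check.names = FALSE)
  expect_equal(names(got), c("parameter", "Epi", "PD", "RD", "Hypo",
                             "Muscle"))
  expect_equal(got$RD[got$parameter == "m_fd"], 1150)
})

test_that("the command-line wrapper prints and exports the table", {
  cli <- system.file("exec", "skinphase", package = "skinphase")
  expect_true(nzchar(cli))
  f <- tempfile(fileext = ".csv")
  out <- system2("Rscript", c(cli, "params", "--csv", f),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(f))
  got <- utils::read.csv(f)
  expect_equal(got$RD[got$parameter == "mu0"], 0.668e-2)
})
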