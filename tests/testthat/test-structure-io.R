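test_that("a toy PDB round-trips atoms and coordinates identically", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path)
  st <- read_structure(path)
  expect_equal(nrow(st$topology), 3)
  expect_equal(st$topology$name, c("N", "CA", "O"))
  expect_equal(st$topology$chain_id, c("A", "A", "B"))
  expect_equal(st$topology$residue_number, c(1, 1, 2))
  expect_equal(st$frame[1, ], c(10, 10, 10))
  expect_equal(st$frame[2, 1], 11.4)
  expect_true(all(st$topology$partial_charge == 0))
  expect_false(any(st$topology$is_donor_hydrogen))
})

test_that("multi-MODEL PDBs expose the first model and a full trajectory", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- c("MODEL        1", toy_pdb_text()[1:3], "ENDMDL",
             "MODEL        2",
             sub("10\\.000  10\\.000  10\\.000", "10.500  10.000  10.000",
                 toy_pdb_text()[1]),
             toy_pdb_text()[2:3], "ENDMDL", "END")
  writeLines(lines, path)
  st <- read_structure(path)
  expect_equal(st$n_models, 2)
  expect_equal(st$frame[1, 1], 10)
  traj <- read_trajectory(st$topology, path, frame_interval = 0.02)
  expect_equal(nrow(traj$xyz), 2)
  expect_equal(traj$times, c(0, 0.02))
  expect_equal(frame_coords(traj, 2)[1, 1], 10.5)
})

test_that("insertion codes keep residues distinct", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  CA  ALA A  52      10.000  10.000  10.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A  52A     14.000  10.000  10.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A  52B     18.000  10.000  10.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  st <- read_structure(path)
  keys <- paste0(st$topology$chain_id, st$topology$residue_number, st$topology$insert)
  expect_equal(length(unique(keys)), 3)
  expect_setequal(st$topology$insert, c("", "A", "B"))
})

test_that("read_structure errors on missing or empty files", {
  expect_error(read_structure("no/such/file.pdb"), "not found")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", path)
  expect_error(read_structure(path))
})

test_that("trajectory frame times default to multiples of the frame interval", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- unlist(lapply(1:5, function(m) {
    c(sprintf("MODEL %8d", m), toy_pdb_text()[1:3], "ENDMDL")
  }))
  writeLines(c(lines, "END"), path)
  st <- read_structure(path)
  traj <- read_trajectory(st$topology, path, frame_interval = 0.02)
  expect_equal(traj$times, c(0, 0.02, 0.04, 0.06, 0.08))
  single <- read_trajectory(st$topology, withr::local_tempfile(fileext = ".pdb") |>
                              write_toy_pdb())
  expect_equal(nrow(single$xyz), 1)
})

test_that("trajectory writer/reader round trip preserves coordinates to format precision", {
  set.seed(42)
  n <- 7
  topo <- make_topology(n, chain_id = rep("A", n),
                        residue_number = rep(1:4, length.out = n),
                        element = sample(c("C", "N", "O"), n, TRUE))
  topo$residue_name <- "ALA"
  xyz <- matrix(round(runif(3 * n * 4, -50, 50), 3), nrow = 4)
  traj <- new_trajectory(topo, xyz, times = (0:3) * 0.02)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, path)
  back <- read_trajectory(topo, path, frame_interval = 0.02)
  expect_equal(back$xyz, traj$xyz, tolerance = 1e-12)
  expect_equal(nrow(back$xyz), 4)
})

test_that("atom-count mismatches are reported with both counts", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path)
  topo4 <- make_topology(4, rep("A", 4), 1:4, rep("C", 4))
  expect_error(read_trajectory(topo4, path), "4")
})

test_that("charge tables annotate by atom_id and by chain/resnum/name keys", {
  topo <- make_topology(8, chain_id = rep(c("A", "B"), each = 4),
                        residue_number = rep(1:2, 4),
                        element = rep(c("C", "N", "O", "H"), 2),
                        name = c("C1", "N1", "O1", "H1", "C2", "N2", "O2", "H2"))
  tab <- tibble::tibble(atom_id = 7, partial_charge = -0.27)
  topo2 <- suppressMessages(apply_charge_table(topo, tab))
  expect_equal(topo2$partial_charge[7], -0.27)
  expect_equal(topo2$partial_charge[-7], rep(0, 7))

  keyed <- tibble::tibble(chain = "A", resnum = 2, atom_name = "N1",
                          partial_charge = 0.4, is_acceptor = TRUE)
  topo3 <- suppressMessages(apply_charge_table(topo, keyed))
  expect_equal(topo3$partial_charge[2], 0.4)
  expect_true(topo3$is_acceptor[2])
})

test_that("empty charge tables warn and leave charges at zero", {
  topo <- make_topology(3, rep("A", 3), 1:3, c("C", "N", "O"))
  expect_warning(out <- apply_charge_table(topo, tibble::tibble()), "Empty")
  expect_true(all(out$partial_charge == 0))
})

test_that("unmatched keys warn and duplicate keys error", {
  topo <- make_topology(3, rep("A", 3), 1:3, c("C", "N", "O"))
  expect_warning(suppressMessages(
    apply_charge_table(topo, tibble::tibble(atom_id = c(2, 99),
                                            partial_charge = c(0.1, 0.2)))),
    "match no atom")
  expect_error(
    apply_charge_table(topo, tibble::tibble(atom_id = c(2, 2),
                                            partial_charge = c(0.1, 0.2))),
    "Duplicate")
})

test_that("a full synthetic annotation round-trips through the TSV format", {
  set.seed(7)
  n <- 20
  topo <- make_topology(n, chain_id = sample(c("A", "B"), n, TRUE),
                        residue_number = sample(1:5, n, TRUE),
                        element = sample(c("C", "N", "O", "H", "S"), n, TRUE))
  q <- round(runif(n, -0.8, 0.8), 4)
  don <- topo$element == "H" & runif(n) < 0.5
  acc <- topo$element %in% c("N", "O", "S")
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(atom_id = 1:n, partial_charge = q,
                                  is_donor_h = don, is_acceptor = acc), path)
  out <- suppressMessages(apply_charge_table(topo, read_charge_table(path)))
  expect_equal(out$partial_charge, q)
  expect_equal(out$is_donor_hydrogen, don)
  expect_equal(out$is_acceptor, acc)
})

test_that("donor/acceptor inference flags covalent hydrogens and N/O/S", {
  topo <- make_topology(4, rep("A", 4), c(1, 1, 2, 2), c("N", "H", "C", "O"))
  frame <- rbind(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0), c(9, 0, 0))
  out <- infer_donors_acceptors(topo, frame)
  expect_equal(out$is_donor_hydrogen, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$is_acceptor, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("domain resolution selects exactly the in-range atoms, in order", {
  n <- 24
  topo <- make_topology(n, chain_id = rep("G", n),
                        residue_number = rep(1:240, length.out = n) * 10,
                        element = rep("C", n))
  topo$residue_number <- seq(10, 240, by = 10)
  v <- resolve_domain(domain_spec("Vg", "G", c(1, 119)), topo)
  c_ <- resolve_domain(domain_spec("Cg", "G", c(120, 240)), topo)
  expect_equal(v, topo$atom_id[topo$residue_number <= 119])
  expect_equal(sort(c(v, c_)), topo$atom_id)      # partition of the chain
  expect_length(intersect(v, c_), 0)
  expect_error(resolve_domain(domain_spec("X", "Z", c(1, 10)), topo), "chain 'Z'")
  expect_error(resolve_domain(domain_spec("X", "G", c(500, 600)), topo), "zero atoms")
})
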