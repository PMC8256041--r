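# Fixture builders and independent brute-force oracles used across tests.

# minimal topology tibble from parallel vectors
make_topology <- function(n, chain_id, residue_number, element,
                          partial_charge = rep(0, n),
                          is_donor_hydrogen = rep(FALSE, n),
                          is_acceptor = rep(FALSE, n),
                          name = NULL, insert = rep("", n)) {
  tibble::tibble(
    atom_id = seq_len(n), serial = seq_len(n),
    name = name %||% paste0(element, seq_len(n)),
    element = element, chain_id = chain_id,
    residue_number = residue_number, insert = insert,
    residue_name = "UNK",
    partial_charge = partial_charge,
    is_donor_hydrogen = is_donor_hydrogen, is_acceptor = is_acceptor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random interface fixture: n atoms split between chains A and B in a box,
# with random charges and donor/acceptor flags
random_fixture <- function(n, seed, box = 8) {
  set.seed(seed)
  elements <- sample(c("H", "C", "N", "O", "S"), n, replace = TRUE)
  chain <- sample(c("A", "B"), n, replace = TRUE)
  if (!any(chain == "A")) chain[1] <- "A"
  if (!any(chain == "B")) chain[n] <- "B"
  topo <- make_topology(
    n, chain_id = chain,
    residue_number = sample(1:6, n, replace = TRUE),
    element = elements,
    partial_charge = round(runif(n, -0.6, 0.6), 3),
    is_donor_hydrogen = elements == "H" & runif(n) < 0.7,
    is_acceptor = elements %in% c("N", "O", "S") & runif(n) < 0.8)
  frame <- matrix(runif(3 * n, 0, box), ncol = 3)
  list(topology = topo, frame = frame,
       set_a = topo$atom_id[topo$chain_id == "A"],
       set_b = topo$atom_id[topo$chain_id == "B"])
}

# all-pairs O(n^2) oracle for hydrogen-bond detection (canonical keys)
oracle_hbond_keys <- function(frame, topo, set_a, set_b, cutoff) {
  keys <- character()
  for (i in set_a) for (j in set_b) {
    d <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    ok <- (topo$is_donor_hydrogen[i] && topo$is_acceptor[j]) ||
      (topo$is_donor_hydrogen[j] && topo$is_acceptor[i])
    # a pair qualifying in both directions is still one contact per direction
    if (d < cutoff) {
      if (topo$is_donor_hydrogen[i] && topo$is_acceptor[j]) {
        keys <- c(keys, paste0("HB:", min(i, j), "-", max(i, j)))
      }
      if (topo$is_donor_hydrogen[j] && topo$is_acceptor[i]) {
        keys <- c(keys, paste0("HB:", min(i, j), "-", max(i, j)))
      }
    }
  }
  sort(unique(keys))
}

# all-pairs oracle for nonpolar contacts at residue granularity
oracle_np_keys <- function(frame, topo, set_a, set_b, cutoff, qmax) {
  res_of <- function(i) paste0(topo$chain_id[i], topo$residue_number[i], topo$insert[i])
  keys <- character()
  for (i in set_a) for (j in set_b) {
    if (abs(topo$partial_charge[i]) >= qmax) next
    if (abs(topo$partial_charge[j]) >= qmax) next
    d <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    if (d < cutoff) {
      ra <- res_of(i); rb <- res_of(j)
      keys <- c(keys, paste0("NP:", min(ra, rb), "-", max(ra, rb)))
    }
  }
  sort(unique(keys))
}

# high-resolution numerical SASA oracle for two overlapping spheres:
# exact spherical-cap closed form
two_sphere_sasa_exact <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  # height of the cap of sphere 1 buried inside sphere 2
  cap1 <- 2 * pi * R1 * (R1 - (d^2 + R1^2 - R2^2) / (2 * d))
  cap2 <- 2 * pi * R2 * (R2 - (d^2 + R2^2 - R1^2) / (2 * d))
  4 * pi * R1^2 - cap1 + 4 * pi * R2^2 - cap2
}

# three-atom toy PDB text fixture
toy_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1      10.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.400  10.000  10.000  1.00  0.00           C",
    "ATOM      3  O   GLY B   2      12.000  11.000  10.000  1.00  0.00           O",
    "END")
}

write_toy_pdb <- function(path, lines = toy_pdb_text()) {
  writeLines(lines, path)
  path
}
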