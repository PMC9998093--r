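# a minimal hand-built ensemble: one subunit architecture row per bead
two_bead_ensemble <- function(d_nm = 2) {
  beads <- tibble::tibble(bead = 1:2, subunit = c(1L, 1L),
                          domain = c("core", "math"),
                          binding_site = c(FALSE, TRUE), mass = 1)
  coords <- array(0, c(1, 2, 3))
  coords[1, 2, 3] <- d_nm
  oligomer_ensemble(2, numeric(0), matrix(numeric(0), 1, 0),
                    coords = coords, beads = beads, check_i0 = FALSE)
}

test_that("radius of gyration and domain distances match closed forms", {
  ens <- two_bead_ensemble(2)
  g <- geometry_summary(ens)
  # two unit masses 2 nm apart: Rg = 1 nm
  expect_equal(g$per_conformer$rg, 1)
  expect_equal(g$math_dist$dist, 2)
  spec <- synthetic_spec(jitter = 0, state_pops = c(1, 0, 0))
  helix <- generate_oligomer(spec, 5, 3)
  gh <- geometry_summary(helix)
  expect_equal(gh$per_conformer$ree, rep(3.1 * 4, 3))
  # with w = w0 the weighted means coincide
  expect_equal(gh$means$mean_w, gh$means$mean_w0)
  expect_error(geometry_summary(raw_ensemble(matrix(1, 2, 3))), "coordinates")
})

test_that("geometry weighted means respond to the weights", {
  spec <- synthetic_spec()
  ens <- generate_oligomer(spec, 4, 16, seed = 41)
  g0 <- geometry_summary(ens)
  w <- rep(0, 16); w[which.max(g0$per_conformer$ree)] <- 1
  g1 <- geometry_summary(ens, weights = w)
  expect_equal(g1$means$mean_w[g1$means$observable == "ree"],
               max(g0$per_conformer$ree))
})

test_that("power-law fit recovers exact scaling laws", {
  N <- c(2, 4, 8, 16, 32, 60)
  f1 <- fit_power_law(N, 3.1 * N)
  expect_equal(f1$R0, 3.1, tolerance = 1e-8)
  expect_equal(f1$nu, 1, tolerance = 1e-8)
  f2 <- fit_power_law(N, 2 * N^0.5)
  expect_equal(f2$R0, 2, tolerance = 1e-8)
  expect_equal(f2$nu, 0.5, tolerance = 1e-8)
  expect_error(fit_power_law(N[1:2], c(1, 2)), ">= 3")
  expect_error(fit_power_law(N, -3.1 * N), "positive")
  td <- tidy(f1)
  expect_equal(td$estimate, c(3.1, 1), tolerance = 1e-6)
})

test_that("subsampling thresholds follow the min/max/mean prescriptions", {
  # conformers whose end-to-end distances are uniform on [10, 20] nm
  spec <- synthetic_spec(jitter = 0, state_pops = c(1, 0, 0))
  base <- generate_oligomer(spec, 2, 1)
  n <- 21
  coords <- array(0, c(n, dim(base$coords)[2], 3))
  scales <- seq(10, 20, length.out = n) / (3.1 * 1)
  for (k in 1:n) coords[k, , ] <- base$coords[1, , ] * scales[k]
  ens <- oligomer_ensemble(2, numeric(0), matrix(numeric(0), n, 0),
                           coords = coords, beads = base$beads, check_i0 = FALSE)
  g <- geometry_summary(ens)
  expect_equal(range(g$per_conformer$ree), c(10, 20), tolerance = 1e-9)
  ext <- subsample_ensemble(ens, "extended_ee", geometry = g)
  # threshold = max - (max - mean)/2 = 20 - 5/2 = 17.5
  expect_equal(attr(ext, "threshold"), 17.5)
  expect_true(all(g$per_conformer$ree[attr(ext, "selected")] > 17.5))
  cmp <- subsample_ensemble(ens, "compact_ee", geometry = g)
  expect_equal(attr(cmp, "threshold"), 12.5)
  # repeated extended-selection never widens the selected range
  g2 <- geometry_summary(ext)
  ext2 <- subsample_ensemble(ext, "extended_ee", geometry = g2)
  expect_gte(attr(ext2, "threshold"), attr(ext, "threshold"))
})

test_that("subsampling the mobile-domain states separates a bimodal ensemble", {
  spec <- synthetic_spec(jitter = 0.02,
                         state_pops = c(docked_a = 0.5, docked_b = 0, extended = 0.5))
  ens <- generate_oligomer(spec, 2, 200, seed = 44)
  st <- attr(ens, "states")
  extended_frames <- which(rowMeans(st == 3) == 1)
  got <- subsample_ensemble(ens, "math_extended")
  # frames whose subunits are all extended sit above 5.2 nm
  expect_true(all(extended_frames %in% attr(got, "selected")))
  docked <- subsample_ensemble(ens, "math_compact")
  expect_true(all(rowMeans(st[attr(docked, "selected"), , drop = FALSE] == 1) > 0))
  # identical frames select nothing under the strict end-to-end rules
  const <- generate_oligomer(synthetic_spec(jitter = 0, state_pops = c(1, 0, 0)), 3, 4)
  expect_error(subsample_ensemble(const, "extended_ee"), "empty selection")
})

test_that("motif scanning applies the two degenerate patterns", {
  # P1-only: position 4 polar-not-ST, position 5 ST
  expect_equal(find_motifs("ADSDT")$pattern, "P1")
  # P2-only: position 4 ST, position 5 polar-not-ST
  expect_equal(find_motifs("ADSTQ")$pattern, "P2")
  # a window satisfying both patterns is reported once per pattern
  both <- find_motifs("ADSTT")
  expect_equal(sort(both$pattern), c("P1", "P2"))
  expect_equal(both$start, c(1L, 1L))
  # negative control: K not allowed at position 1
  expect_equal(nrow(find_motifs("KDSTT")), 0)
  # overlapping windows are all reported (C is both hydrophobic and polar)
  hits <- find_motifs("ACSTTS")
  expect_true(all(hits$start %in% c(1L, 2L)))
  expect_gt(length(unique(hits$start)), 1)
  expect_error(find_motifs("ADSXT"), "non-standard")
})

test_that("motif spacing on a straight chain equals the residue separation times the bond length", {
  seqs <- "ADSDTGGGGGADSDTGGGGGGGGGGADSDT"
  motifs <- find_motifs(seqs)
  expect_equal(motifs$start, c(1L, 11L, 26L))
  nres <- nchar(seqs)
  traj <- array(0, c(3, nres, 3))
  for (fr in 1:3) traj[fr, , 1] <- (seq_len(nres) - 1) * 0.38
  ms <- motif_spacing(traj, motifs)
  expect_equal(ms$pair_means$sep_residues, c(10, 15))
  expect_equal(ms$pair_means$mean_dist, c(10, 15) * 0.38, tolerance = 1e-12)
  expect_equal(nrow(ms$distances), 6)  # 2 pairs x 3 frames
  # frame order is irrelevant for the pooled distances
  perm <- traj[c(2, 3, 1), , , drop = FALSE]
  expect_equal(sort(motif_spacing(perm, motifs)$distances$dist),
               sort(ms$distances$dist))
  expect_error(motif_spacing(traj, motifs[1, ]), ">= 2 motifs")
})

test_that("FASTA sequences round-trip into the motif scanner", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sub1", "ADSDTGGADSTQ", ">sub2", "KKKKK"), path)
  seqs <- read_fasta_sequences(path)
  expect_equal(length(seqs), 2)
  expect_equal(nrow(find_motifs(seqs[["sub1"]])), 2)
  expect_equal(nrow(find_motifs(seqs[["sub2"]])), 0)
})

test_that("Gaussian decomposition of the mobile-domain distances finds the three states", {
  spec <- synthetic_spec(jitter = 0.05)
  ens <- generate_oligomer(spec, 4, 400, seed = 46)
  g <- geometry_summary(ens)
  dec <- decompose_math_states(g$math_dist)
  expect_equal(nrow(dec$components), 3)
  expect_equal(dec$components$mean, unname(spec$state_dist), tolerance = 0.05)
  expect_true(all(dec$representatives$component %in% 1:3))
})
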