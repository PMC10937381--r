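# Shared builders for synthetic fixtures. All fixtures are generated in code.

plasmid_contigs <- function(L = 20000L, circular = FALSE) {
  contig_table("chrS", L, circular = circular)
}

five_sites <- function() {
  anchor_set("chrS", c(3000L, 6500L, 10000L, 13500L, 17000L), "+")
}

# generate -> classify -> shift -> filter in one go
synth_filtered_pairs <- function(cfg, gt = make_ground_truth(cfg)) {
  pp <- simulate_ligation_pairs(gt)
  pp <- shift_to_dyad(classify_orientation(pp), contigs = cfg$contigs)
  list(gt = gt, flt = filter_pairs(pp))
}

# minimal hand-built bead model for annealing unit tests
toy_bead_model <- function(coords, bonds, radii = rep(0.5, nrow(coords)),
                           angles = matrix(integer(0), 0, 3), k_angle = 12.5) {
  structure(list(beads = data.frame(kind = rep("dna_linker", nrow(coords)),
                                    nucleosome = NA_integer_),
                 coords = coords, bonds = bonds, angles = angles,
                 radii = radii,
                 entry = integer(0), exit = integer(0),
                 histone_idx = list(), dyads = integer(0),
                 contig = "toy", geometry = bead_geometry(),
                 k_angle = k_angle),
            class = "bead_model")
}
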