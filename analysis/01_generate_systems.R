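#!/usr/bin/env Rscript
# Builds the study systems and writes structures plus ground-truth manifests.
suppressPackageStartupMessages(library(thzbind))
dir.create("results/systems", showWarnings = FALSE, recursive = TRUE)

for (f0 in c(10, 34.5, 80)) {
  sys <- make_harmonic_probe(f0)
  stem <- file.path("results/systems", sprintf("probe_%s", gsub("\\.", "p", f0)))
  write_structure(sys, paste0(stem, ".pdb"))
  write_manifest(sys, paste0(stem, ".json"))
}

hg <- make_host_guest(n_donors = 4, n_hydrophobic = 6, well_depth = -50,
                      seed = 1)
write_structure(hg, "results/systems/host_guest.pdb")
write_manifest(hg, "results/systems/host_guest.json")
man <- attr(hg, "manifest")
message("host-guest: ", hg$n_atoms, " atoms; t0 binding energy ",
        round(man$well_depth_achieved, 2), " kJ/mol; switchable contacts: ",
        paste(man$switchable_pair_ids, collapse = ", "))

ion_box <- make_toy_box(hg, 8.0, salt_molar = 0.15, seed = 1)
write_structure(ion_box, "results/systems/host_guest_ions.pdb")
write_manifest(ion_box, "results/systems/host_guest_ions.json")
message("ionized box: ", attr(ion_box, "manifest")$n_cations, " cations / ",
        attr(ion_box, "manifest")$n_anions, " anions at 0.15 M")
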