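# Small, fast scene specifications for unit tests; the acceptance tests
# exercise the full default composition.

small_composition <- function() {
  # mix of charges including neutrals for the vapor plant (0-based ids):
  # pyruvate(-1), glycerol(0), succinate(-2), catechol(0), benzoate(-1),
  # indole(0), glucose(0), glycylcysteine(0), sinapate(-1), catechin(0)
  c(0L, 1L, 2L, 3L, 4L, 6L, 10L, 13L, 17L, 19L)
}

small_spec <- function(seed = 1,
                       mineral_kind = "SMECTITE_LIKE",
                       counterion = "NA",
                       counts = c(direct = 2, cation_bridged = 1,
                                  som_bridged = 2, free = 3,
                                  interface = 1, vapor = 1),
                       n_water = 900, n_ligand_exchange = 0L, ...) {
  scene_spec(lx = 75, ly = 75, lz = 100,
             mineral_kind = mineral_kind, counterion = counterion,
             counts = counts, n_water = n_water, seed = seed,
             n_ligand_exchange = n_ligand_exchange,
             composition = small_composition(), ...)
}
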