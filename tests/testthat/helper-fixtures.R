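# Shared fixture builders (everything is generated in code).

core_tree <- function() {
  parse_glycan(c("HexNAc", "  HexNAc", "    Hex", "      Hex", "      Hex"))
}

chain_tree <- function(codes) {
  node <- glycan_node(codes[length(codes)])
  for (code in rev(codes[-length(codes)])) node <- glycan_node(code, list(node))
  node
}

# random tree for round-trip properties (uniform growth, caller seeds)
rnd_tree <- function(size, classes = MONO_CODES) {
  glycoscout:::random_glycan_tree(size, classes, forced_core = FALSE)
}

toy_spectrum <- function(mz, intensity = NULL, pmz = 900, z = 2L, ...) {
  if (is.null(intensity)) intensity <- rep(100, length(mz))
  spectrum("toy", pmz, z, mz, intensity, ...)
}

# small glycan database: N-core + simple extensions
toy_glycan_db <- function() {
  list(
    glycan_record(core_tree(), id = "core", link_type = "N"),
    glycan_record(glycan_node("HexNAc", list(
      glycan_node("HexNAc", list(
        glycan_node("Hex", list(
          glycan_node("Hex", list(glycan_node("Hex"))),
          glycan_node("Hex")
        ))
      ))
    )), id = "core+hex", link_type = "N"),
    glycan_record(chain_tree(c("HexNAc", "Hex", "NeuAc")), id = "sialyl",
                  link_type = "N")
  )
}
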