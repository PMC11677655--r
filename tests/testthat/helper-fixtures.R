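fixture_registry <- function() {
  load_registry(system.file("extdata", "table6_properties.csv",
                            package = "nanoaroma"))
}

fixture_composition <- function() {
  read_composition(system.file("extdata", "table2_composition.csv",
                               package = "nanoaroma"))
}

# minimal two-compound registry built in code, for arithmetic-sized cases
toy_registry <- function() {
  compounds <- data.frame(
    name = c("α-Pinene", "β-Caryophyllene", "Linalool"),
    formula = c("C10H16", "C15H24", "C10H18O"),
    molar_mass_g_mol = c(136.23, 204.35, 154.25),
    vapor_pressure_pa = c(513, 4, 21),
    odor_threshold_mg_m3 = c(0.240, 1.500, NA),
    density_kg_m3 = c(860, 907, NA),
    retention_index = c(NA_real_, NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
  compounds$families <- list("woody", c("woody", "oriental"), "floral")
  compounds$nuances <- list("pine", c(NA_character_, NA_character_),
                            NA_character_)
  compound_registry(compounds, source = "toy")
}
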