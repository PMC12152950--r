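## Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## Ten small molecules, two of which carry an oxamide (NC(=O)C(=O)N) group.
toy_library10 <- function() {
  molecule_library(
    id = paste0("t", 1:10),
    smiles = c(
      "c1ccccc1",              # benzene
      "C1CCCCC1",              # cyclohexane
      "Cc1ccccc1",             # toluene
      "NC(=O)C(=O)Nc1ccccc1",  # phenyl oxamide
      "CNC(=O)C(=O)NC",        # dimethyl oxamide
      "CC(=O)Nc1ccccc1",       # acetanilide (amide, not oxamide)
      "OCCO",                  # ethylene glycol
      "c1ccncc1",              # pyridine
      "CC(=O)OC",              # methyl acetate
      "CCN"                    # ethylamine
    ),
    compute_scaffolds = FALSE
  )
}

## A small campaign (one scaffold, one site) for cheap oracle/AL tests.
small_campaign <- function(noise_sd = 0, seed = 7) {
  frags <- c("", "C", "CC", "F", "Cl", "OC", "CO", "N")
  lib <- generate_analog_library(
    "O=C(c1cc2ccccc2[nH]1)N1CCCC1({R1})", list(R1 = frags),
    n_max = 100, seed = seed, id_prefix = "sm")
  contrib <- stats::setNames(seq(-1.5, 1.5, length.out = 7),
                             paste0("R1=", frags[-1]))
  spec <- synthetic_oracle_spec(base_dg = -6, group_contributions = contrib,
                                noise_sd = noise_sd, seed = seed)
  list(library = lib, spec = spec)
}

## Default campaign at full scale (used by AL enrichment checks); cached
## because library enumeration dominates the cost.
enrichment_fixture <- function() {
  fixture("enrichment", function() {
    cfg <- pipeline_config(seed = 2024)
    camp <- default_campaign(cfg)
    feats <- list(ecfp6_2048 = featurize(camp$library, "ecfp6_2048"))
    list(library = camp$library, truth = camp$truth, features = feats)
  })
}

expect_setequal_chr <- function(a, b) {
  expect_setequal(as.character(a), as.character(b))
}

.canon <- function(s) alfe:::.ob_canonical(s)
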