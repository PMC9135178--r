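# Classed conditions so callers can branch on failure modes.

abort_ncm <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ncmetab_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

invalid_smiles <- function(smiles, why = "cannot be parsed or sanitized") {
  abort_ncm("invalid_smiles",
            sprintf("invalid SMILES '%s': %s", smiles, why),
            smiles = smiles)
}
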