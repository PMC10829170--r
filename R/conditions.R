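# Structured condition constructors. Every user-facing failure mode gets a
# dedicated condition class so callers (and tests) can discriminate them.

abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "contrastDDI_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

parse_error       <- function(smiles, why = "not a valid SMILES string") {
  abort("parse_error", sprintf("cannot parse %s: %s", deparse(smiles), why),
        smiles = smiles)
}
io_error          <- function(msg) abort("io_error", msg)
schema_error      <- function(msg) abort("schema_error", msg)
unknown_token_error <- function(char, smiles) {
  abort("unknown_token_error",
        sprintf("character %s in %s is not in the vocabulary",
                deparse(char), deparse(smiles)),
        char = char, smiles = smiles)
}
shape_error       <- function(msg) abort("shape_error", msg)
config_error      <- function(msg) abort("config_error", msg)
value_error       <- function(msg) abort("value_error", msg)
degenerate_vector_error <- function(msg = "zero-norm vector") {
  abort("degenerate_vector_error", msg)
}
degenerate_split_error <- function(msg) abort("degenerate_split_error", msg)
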