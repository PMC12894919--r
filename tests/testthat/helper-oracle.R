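# Hand-coded boolean oracle: one direct expression per pathway, written
# straight from the marker table, independent of the rule engine.
oracle_calls <- function(kos) {
  has <- function(...) all(c(...) %in% kos)
  any_of <- function(...) any(c(...) %in% kos)
  n_of <- function(v) sum(v %in% kos)
  c(CBB = has("K00855") && has("K01601") && has("K01783"),
    rTCA = has("K15230", "K15231") ||
      (has("K15233", "K15232") && has("K15234")),
    WL = (has("K00198") && has("K14138")) ||
      (has("K00192", "K00195") && has("K00193", "K00194", "K00197")),
    "3HP" = has("K14468") && has("K14471", "K14472"),
    "3HP4HB" = (has("K15017") && has("K15039") && has("K14534")) ||
      (has("K18603", "K18604", "K18605") && has("K18602") && has("K14534")),
    DC4HB = has("K01595") && any_of("K01676", "K01677", "K01678") &&
      any_of("K18861", "K14467") && has("K14534"),
    rGly = n_of(c("K00283", "K00282", "K02437", "K00605")) >= 3 &&
      n_of(c("K10671", "K10672", "K00384", "K21577", "K21576",
             "K03671", "K10670")) >= 5)
}

# The glycine cleavage system and glycine reductase subunit KO sets.
RGLY_GCS <- c("K00283", "K00282", "K02437", "K00605")
RGLY_GR <- c("K10671", "K10672", "K00384", "K21577", "K21576", "K03671",
             "K10670")
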