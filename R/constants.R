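# Shared character tables, kept in a file that loads before its users.

ACCENT_FROM <- "àáâãäåçèéêëìíîïñòóôõöùúûüýÿ"
ACCENT_TO   <- "aaaaaaceeeeiiiinooooouuuuyy"

FRENCH_MONTHS <- c(
  "janvier", "fevrier", "mars", "avril", "mai", "juin",
  "juillet", "aout", "septembre", "octobre", "novembre", "decembre"
)

FRENCH_MONTHS_ACCENTED <- c(
  "janvier", "février", "mars", "avril", "mai", "juin",
  "juillet", "août", "septembre", "octobre", "novembre", "décembre"
)
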