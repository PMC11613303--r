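# Physical constants and small numeric helpers shared across the package.

## Boltzmann constant in eV/K; activation energies are carried in eV.
.kB <- 8.617333262e-5

## Temperatures cross the user interface in degrees Celsius and are converted
## to Kelvin only inside Arrhenius exponentials.
celsiusToKelvin <- function(tC) tC + 273.15

## Arrhenius factor exp(-E / (kB * T_K)), vectorised over temperature.
arrhenius <- function(tC, e_act) exp(-e_act / (.kB * celsiusToKelvin(tC)))

## Derive a stage seed from the root seed. Keeps results < 2^31 so the value
## is always a valid R integer seed.
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Polynomial rolling hash of a character scalar, returned as hex.
## Used to fingerprint configurations in run manifests.
strHash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
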