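# shared fixtures: everything is generated in code

ref_grid <- function() build_grid(250e3, 8)

ref_model <- function() tuna_reference_model()

# a two-dispersion-style circuit used in several tests
demo_circuit <- function() {
  series_network(resistor(100),
                 parallel_network(resistor(200), cpe_model(1e-6, 0.5)))
}

rand_spectrum <- function(nf) {
  complex(real = stats::runif(nf, -2, 2), imaginary = stats::runif(nf, -2, 2))
}

rel_err <- function(x, ref) max(abs(x - ref)) / max(abs(ref))
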