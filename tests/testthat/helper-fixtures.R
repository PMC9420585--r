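# shared fixtures: noiseless generation settings and tiny training sets

no_noise <- function() noise_params(0, 0, 0, 0.25, 0)

# small clean dataset cycling through the pulse types
clean_records <- function(n, seed0 = 100) {
  lapply(seq_len(n), function(i) {
    generate_record(pulse_types[(i - 1L) %% 7L + 1L],
                    noise = no_noise(), seed = seed0 + i)
  })
}

signals_of <- function(recs) lapply(recs, function(r) r$record$samples)
labels_of <- function(recs) lapply(recs, `[[`, "labels")
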