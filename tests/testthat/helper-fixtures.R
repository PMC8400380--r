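# Shared fixture builders (everything generated in code at test time).

# a small random complex acquisition; M divisible by 4
randomAcq <- function(M = 16L, K = 24L, gainDb = 0, seed = 1) {
  set.seed(seed)
  z <- matrix(complex(real = rnorm(M * K), imaginary = rnorm(M * K)), M, K)
  KSpaceAcquisition(z, gainDb = gainDb)
}

# the default study receiver (quantization-limited lowest gain)
studyReceiver <- function() {
  receiverModel(preNoiseSigma = 80, postNoiseSigma = 40,
                adcBits = 12L, fullScale = 1.2e6)
}

# low-noise, unquantized receiver for estimator-accuracy checks
cleanReceiver <- function() {
  receiverModel(preNoiseSigma = 5, postNoiseSigma = 2, adcBits = 0L)
}
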