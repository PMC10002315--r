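test_that("a 250 Hz tone concentrates power in the low band", {
  sp <- spectral_features(sine_recording(250))
  b1 <- sp$band_power_0_500$values
  tot4k <- b1 + sp$band_power_500_1000$values + sp$band_power_1000_4000$values
  expect_true(all(b1 / tot4k >= 0.99))
  expect_true(all(abs(sp$centroid$values - 250) < 5))
})

test_that("equal-power tones average to the midpoint centroid", {
  rate <- 11025
  t <- (1:5513) / rate
  rec <- audio_recording(0.4 * sin(2 * pi * 300 * t) +
                           0.4 * sin(2 * pi * 900 * t), rate)
  sp <- spectral_features(rec)
  expect_true(all(abs(sp$centroid$values - 600) < 10))
})

test_that("spectral flux of a stationary tone is near zero after frame one", {
  sp <- spectral_features(sine_recording(400, duration = 0.4))
  fl <- sp$flux$values
  expect_equal(fl[1], 0)
  expect_true(all(fl[-1] < 1e-3))
})

test_that("band powers partition the energy of a band-limited signal", {
  rec <- sine_recording(800, duration = 0.4)
  sp <- spectral_features(rec)
  frames <- voicesym:::frame_spectra(rec)
  total <- colSums(frames$power)
  three <- sp$band_power_0_500$values + sp$band_power_500_1000$values +
    sp$band_power_1000_4000$values
  expect_true(all(three <= total + 1e-9))
  expect_true(all(three / total > 0.999))   # all energy below 4 kHz
})

test_that("powers scale quadratically and the centroid is scale-invariant", {
  rec <- quick_voice(seed = 6, duration = 0.4)
  rec2 <- audio_recording(rec$samples / 2, rec$rate)
  a <- spectral_features(rec)
  b <- spectral_features(rec2)
  expect_equal(b$band_power_0_500$values, a$band_power_0_500$values / 4,
               tolerance = 1e-10)
  expect_equal(b$rms$values, a$rms$values / 2, tolerance = 1e-10)
  expect_equal(b$centroid$values, a$centroid$values, tolerance = 1e-10)
  expect_equal(b$flux$values, a$flux$values, tolerance = 1e-8)
})

test_that("rates too low for the 1-4 kHz band are rejected", {
  expect_error(spectral_features(audio_recording(rnorm(4000), 8000)),
               "band")
})

test_that("returned MFCCs are invariant to global amplitude scaling", {
  rec <- quick_voice(seed = 7, duration = 0.4)
  m1 <- mfcc(rec)
  m2 <- mfcc(audio_recording(rec$samples * 2, rec$rate))
  expect_equal(m1$values, m2$values, tolerance = 1e-9)
})

test_that("digital silence produces finite constant MFCCs", {
  m <- mfcc(audio_recording(numeric(2205), 11025))
  expect_true(all(is.finite(m$values)))
  expect_equal(max(apply(m$values, 2, sd)), 0)
})

test_that("MFCCs agree with an independent NumPy implementation", {
  rec <- quick_voice(seed = 9, duration = 0.3, snr = 20)
  m <- mfcc(rec)
  smp <- withr::local_tempfile(fileext = ".txt")
  out <- withr::local_tempfile(fileext = ".csv")
  py <- withr::local_tempfile(fileext = ".py")
  write.table(rec$samples, smp, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf('
import numpy as np
x = np.loadtxt(%s); fs = 11025.0
flen, fhop, nfilt, nc = round(0.025*fs), round(0.010*fs), 26, 12
nfr = int(np.floor((len(x)-flen)/fhop))+1
w = 0.54-0.46*np.cos(2*np.pi*np.arange(flen)/(flen-1))
fr = np.stack([x[i*fhop:i*fhop+flen]*w for i in range(nfr)])
nfft = int(2**np.ceil(np.log2(flen)))
P = np.abs(np.fft.rfft(fr, nfft))**2
freqs = np.arange(nfft//2+1)*fs/nfft
mel = lambda f: 2595*np.log10(1+f/700)
imel = lambda m: 700*(10**(m/2595)-1)
edges = imel(np.linspace(0, mel(fs/2), nfilt+2))
fb = np.zeros((nfilt, len(freqs)))
for m_ in range(nfilt):
    lo, mid, hi = edges[m_], edges[m_+1], edges[m_+2]
    up = (freqs>=lo)&(freqs<=mid); dn = (freqs>mid)&(freqs<=hi)
    fb[m_,up] = (freqs[up]-lo)/(mid-lo); fb[m_,dn] = (hi-freqs[dn])/(hi-mid)
E = P @ fb.T
fl = np.maximum(E.max(axis=1, keepdims=True)*1e-8, np.finfo(float).tiny)
L = np.log(np.maximum(E, fl))
k = np.arange(1, nc+1); mm = np.arange(1, nfilt+1)
D = np.sqrt(2/nfilt)*np.cos(np.pi*np.outer(k, mm-0.5)/nfilt)
np.savetxt(%s, L @ D.T, delimiter=",")
', shQuote(smp), shQuote(out)), py)
  status <- system2("python", py)
  expect_equal(status, 0)
  ref <- as.matrix(read.csv(out, header = FALSE))
  dimnames(ref) <- NULL
  got <- m$values
  dimnames(got) <- NULL
  expect_equal(got, ref, tolerance = 1e-8)
})
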