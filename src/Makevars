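PKG_CXXFLAGS = -O3 -march=native -funroll-loops -fno-math-errno -fno-trapping-math
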