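# Hot loops (softmax, GELU) are pure arithmetic so they benefit from -O3;
# appended after the site CXXFLAGS so it takes effect.
CXXFLAGS += -O3 -fno-math-errno
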