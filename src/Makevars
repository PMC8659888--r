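# Kernels are memory-bound scalar loops; build them with full host SIMD
# and associative-math reductions. (Compilation always happens on the
# machine that runs the code.)
%.o: CXXFLAGS += -O3 -march=native -funroll-loops -fno-math-errno -fassociative-math -fno-signed-zeros -fno-trapping-math
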