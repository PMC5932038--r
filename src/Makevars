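# Use the system C++ toolchain.  The conda cross-compiler on this image
# targets a newer glibc sysroot than the host runtime, so its shared
# objects fail to dyn.load; plain C++ with no external libraries, so the
# host g++ works.  Makevars is read before Makeconf, hence `override`.
override CXX = g++
override CXX11 = g++
override CXX14 = g++
override CXX17 = g++
override CXX20 = g++
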