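>SANS_synthetic_scaffold synthetic 461-aa stand-in with motif windows at their native coordinates
STGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNP
STGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNP
STGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNP
LTSSTLSRRLQHLALQNPSTGQNPSTGQNPSTKTKMQKKLERRKGQNPSTGQNPEDGRKS
ARSLSGLQLQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNP
STGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNP
STGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGQNPSTGALLRQEKIDLEALML
STGQNPSTGQNPSTGRKKILGAVRRRRQNPSTGQNPSTGQN
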