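# Coarse representation: every residue is its C-alpha; any residue
# may be matched with any other.
mode grouped
def * CA
* *
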