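not
no
never
none
neither
nor
nothing
nobody
cannot
can't
don't
doesn't
didn't
won't
wouldn't
couldn't
shouldn't
isn't
aren't
wasn't
weren't
hasn't
haven't
hadn't
without
rarely
seldom
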