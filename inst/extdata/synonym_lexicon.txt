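# Synonym lexicon for the overlap screen: one pair per line, whitespace
# separated. Pairs are symmetric; no transitive closure is applied.
# Edit per review; the first pair is the rubric's canonical example.
hyperactive overactive
worried anxious
sad unhappy
afraid fearful
solitary alone
irritable cranky
restless fidgety
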