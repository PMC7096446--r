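>CAP01 synthetic capsid protein with N-terminal R-arm
MRRRNRRAQRRSRRSPSAQRRRAGTGSATAGLVPEQLSTAVDGTSLVKYAVPLTGAAGIT
GDVFAAPLSTHNNTLLGHIVEAIEAHQPVQVKAAVVSGTAMSMDEYLTSIDTGISPSELT
>CAP02 synthetic capsid protein with K-rich arm
MKKKNKKAQKKSKKSPSAQKKKAGTGSATAGLVPEQLSTAVDGTSLVKYAVPLTGAAGIT
GDVFAAPLSTHNNTLLGHIVEAIEAHQPVQVKAAVVSGTAMSMDEYLTSIDTGISPSELT
>ENZ01 synthetic neutral enzyme-like protein
MSTAVDGTSLVAYAVPLTGAAGITGDVFAAPLSTHNNTLLGHIVEAIEAHQPVQVAAAVV
SGTAMSMDEYLTSIDTGISPSELTGQLPDAATVGSAVTAGLVPEQLSTAVDGTSLVAYAV
>ACD01 synthetic acidic protein
MDEEDSEDAQEESEESPSAQDEDAGTGSATAGLVPEQLSTAVDGTSLVEYAVPLTGAAGI
TGDVFAAPLSTHNNTLLGHIVEAIEAHQPVQVEAAVVSGTAMSMDEYLTSIDTGISPSEL
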