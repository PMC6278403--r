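>synthetic_vitellogenin_615aa synthetic stand-in: 615-aa random protein (vertebrate-like composition, seed 615); NOT the E. coioides vitellogenin AAW29031.1 sequence
KGDGNTVMKFPKILDVRNFSSKTVIVCDLTVTKAPKPTLLFSTLRKLNKKNPIHFVFVNF
QENAILVGKAIWLDMMVIRVSYLEGHFNFDKALTIVTKSTERAVLKVNGGTVKICPLKPN
VALLCKRKGFGTPAACRRGKALINFVLVNHDYPYSGNLDQPIGEFLIQGCLEMRGLGKFE
NDKFFTPVGFRLSNIGCINGCALTLVQAPDSLQVFPSANKLHPDAQENAFEVLVYLTLKV
NGETNECQPVDADDSFSLCDARFLINMGKEEKGITGCLGFVIAHFYVQFIPSVGEAFQDL
ELCALTDALFYQAGSGVLADAVTKFQACYYLKQVSLLETKLVSDWHSEGWLANHQVIIHD
EGIGMVMLVSFAFKKQFHVFEPLFQLNHLEQGISEEAKKFGGKEKLITPAANTALKPMLS
SDKEMPYKGVLNLPLFTIKMNVTACLIMRQRLLGMITDLNMVKKIKIGERILRFSHKRTS
IGPASCIHILKAVGGRHAMFPDSKAIKPGSGKIREAAALVGTRCHRGAVDLTMEYLGLKC
DILTLFRFAPIHFLQTKVPLEAQPNMIGGDLVGLTALDQFAALWCISHKELKQDDGKHLM
HAEIQVVVIRTPKIY
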