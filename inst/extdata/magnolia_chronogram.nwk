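(Liriodendron_tulipifera:92.92,(Magnolia_henryi:44.02,(((Magnolia_allenii:13.26,(Magnolia_dodecapetala:12.376,(Magnolia_kichuana:11.492,(Magnolia_lacandonica:10.608,(Magnolia_macrocarpa:9.724,(Magnolia_mexicana:8.84,(Magnolia_ofeliae:7.956,(Magnolia_ovata:7.072,(Magnolia_pastazaensis:6.188,(Magnolia_rimachii:5.304,(Magnolia_silvioi:4.42,(Magnolia_virolinensis:3.536,(Magnolia_wetteri:2.652,(Magnolia_wolfii:1.768,(Magnolia_zamorana:0.884,Magnolia_zoquepopolucae:0.884):0.884):0.884):0.884):0.884):0.884):0.884):0.884):0.884):0.884):0.884):0.884):0.884):0.884):0.884):22.71,((Magnolia_emarginata:10.9,Magnolia_splendens:10.9):3.18,(Magnolia_bankardiorum:10.33,(Magnolia_coronata:6.886666667,(Magnolia_jaenensis:3.443333333,Magnolia_ptaritepuiana:3.443333333):3.443333333):3.443333333):3.75):21.89):2.94,(((Magnolia_sharpii:13.83,(Magnolia_iltisiana:6.915,Magnolia_panamensis:6.915):6.915):9.15,(Magnolia_grandiflora:6,(Magnolia_macrophylla:4.5,(Magnolia_dealbata:3,(Magnolia_rzedowskiana:1.5,Magnolia_vovidesii:1.5):1.5):1.5):1.5):16.98):7.28,(Magnolia_septentrionalis:14.69,(Magnolia_obovata:13.692,(Magnolia_grandis:12.694,(Magnolia_kachirachirai:11.696,(Magnolia_foveolata:10.698,(Magnolia_acuminata:9.7,Magnolia_biondii:9.7):0.998):0.998):0.998):0.998):0.998):15.57):8.65):5.11):48.9);
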