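<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>90000001</PMID>
      <Article>
        <Language>eng</Language>
        <ArticleTitle>Body mass index and blood pressure in adults: a synthetic example citation.</ArticleTitle>
        <Abstract>
          <AbstractText Label="BACKGROUND">Methods: This was a cross-sectional study of 214 overweight/obese patients.</AbstractText>
          <AbstractText Label="METHODS">The aim was to analyze the association between body mass index and blood pressure in this sample.</AbstractText>
          <AbstractText Label="RESULTS">Hernia prevalence was 32.4% in this series.</AbstractText>
        </Abstract>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>90000002</PMID>
      <Article>
        <Language>eng</Language>
        <ArticleTitle>A synthetic citation without an abstract.</ArticleTitle>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>90000003</PMID>
      <Article>
        <Language>eng</Language>
        <ArticleTitle>A synthetic mouse-model citation.</ArticleTitle>
        <Abstract>
          <AbstractText>Weight gain was studied in diet-induced obese mice over twelve weeks.</AbstractText>
        </Abstract>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
</PubmedArticleSet>
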